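# Synthetic barnacle populations with known ground truth.
#
# The generator emulates the sampling design the pipeline is meant for:
# suspended scallop shells far enough apart that barnacles on different
# shells never interact, each carrying a handful of individuals whose penis
# reach determines who can inseminate whom. Responses are generated from the
# same linear mixed-model structure the inference module fits, so generating
# coefficients are recoverable ground truth.

#' Published fixed-effect coefficient sets
#'
#' The fixed-effect estimates (intercept, MGSm, MGSf, body weight) reported
#' for each response in the *Balanus rostratus* field study this pipeline
#' reanalyses: testis + seminal vesicles (mg), penis (mg), ovary (mg), and
#' sex allocation (fraction). They are the generator's default ground truth
#' and the reference values for recovery experiments.
#'
#' @return Named list of four numeric vectors, each with elements
#'   `intercept`, `mgs_m`, `mgs_f`, `body_weight`.
#' @export
default_coefficient_sets <- function() {
  list(
    testis_sv = c(intercept = 17.980, mgs_m = 10.799, mgs_f = -10.501,
                  body_weight = 0.059),
    penis = c(intercept = 0.275, mgs_m = 0.105, mgs_f = -0.097,
              body_weight = 0.0007),
    ovary = c(intercept = 0.761, mgs_m = 40.752, mgs_f = -39.898,
              body_weight = 0.843),
    sex_allocation = c(intercept = 0.1084, mgs_m = 0.0089, mgs_f = -0.0083,
                       body_weight = -0.000020)
  )
}

# Parent (untruncated) normal parameters whose truncation to [lo, hi] has the
# requested mean and SD. The study reports sample moments of bounded data, so
# the truncated distribution -- not its parent -- must match them.
.truncnorm_parent <- function(mean, sd, lo, hi) {
  moments <- function(mu, s) {
    a <- (lo - mu) / s; b <- (hi - mu) / s
    z <- stats::pnorm(b) - stats::pnorm(a)
    da <- stats::dnorm(a); db <- stats::dnorm(b)
    m <- mu + s * (da - db) / z
    v <- s^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
    c(m, sqrt(v))
  }
  obj <- function(p) sum((moments(p[1], exp(p[2])) - c(mean, sd))^2)
  opt <- stats::optim(c(mean, log(sd)), obj, method = "BFGS",
                      control = list(reltol = 1e-14))
  if (opt$value > 1e-8) {
    stop("cannot match truncated-normal moments mean ", mean, ", sd ", sd,
         " on [", lo, ", ", hi, "]")
  }
  c(mean = opt$par[1], sd = exp(opt$par[2]))
}

# noise defaults (shell-level random-intercept SD, residual SD) chosen so
# simulated response ranges bracket the ranges printed for the real data
.default_noise <- function() {
  list(
    testis_sv = c(shell_sd = 10, residual_sd = 20),
    penis = c(shell_sd = 0.15, residual_sd = 0.3),
    ovary = c(shell_sd = 75, residual_sd = 150),
    sex_allocation = c(shell_sd = 0.01, residual_sd = 0.02)
  )
}

#' Generator configuration
#'
#' Defaults reproduce the field study's conditions: 42 shells with 2-7
#' barnacles each; penis lengths truncated-normal with mean 2.77 cm, SD
#' 0.53 cm on \[1.67, 4.46\] cm; operculum (body) weights log-normal with
#' 1st-99th percentiles at the observed range \[244.98, 1807.32\] mg;
#' responses generated from [default_coefficient_sets()] with shell-level
#' random intercepts.
#'
#' @param n_shells Number of substrate shells.
#' @param per_shell_range Integer range (min, max) of barnacles per shell.
#' @param shell_radius_cm Radius of the disc each shell offers, cm. The
#'   default 7.5 cm matches a large scallop shell.
#' @param min_separation_cm Minimum distance between operculum centers, cm;
#'   enforced by rejection sampling.
#' @param penis_mean_cm,penis_sd_cm,penis_bounds_cm Truncated-normal penis
#'   length distribution (cm); `penis_mean_cm`/`penis_sd_cm` are the mean and
#'   SD of the truncated draws themselves (the parent normal is
#'   moment-matched at construction).
#' @param operculum_meanlog,operculum_sdlog Log-normal operculum dry weight
#'   distribution (mg, on the log scale).
#' @param coefficients Named list of generating fixed-effect vectors, one per
#'   response (see [default_coefficient_sets()]).
#' @param noise Named list per response of `c(shell_sd, residual_sd)`.
#' @param mode `"organ_level"`: generate the three organ weights from their
#'   coefficient sets (sex allocation then follows from the organs);
#'   `"allocation_level"`: generate sex allocation directly from its own
#'   coefficient set and back-fill consistent organ weights.
#' @param seed Integer seed; the whole population is a deterministic function
#'   of the config including this seed.
#' @param study A [study_config()] used for the reach geometry when computing
#'   true MGS values.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_shells = 42,
                             per_shell_range = c(2L, 7L),
                             shell_radius_cm = 7.5,
                             min_separation_cm = 0.5,
                             penis_mean_cm = 2.77,
                             penis_sd_cm = 0.53,
                             penis_bounds_cm = c(1.67, 4.46),
                             operculum_meanlog = 6.50057,
                             operculum_sdlog = 0.42965,
                             coefficients = default_coefficient_sets(),
                             noise = .default_noise(),
                             mode = c("organ_level", "allocation_level"),
                             seed = 1L,
                             study = study_config()) {
  mode <- match.arg(mode)
  per_shell_range <- as.integer(round(per_shell_range))
  stopifnot(
    n_shells >= 1,
    length(per_shell_range) == 2, per_shell_range[1] <= per_shell_range[2],
    per_shell_range[1] >= 1, per_shell_range[2] <= 50,
    shell_radius_cm > 0, min_separation_cm >= 0,
    penis_sd_cm >= 0, penis_bounds_cm[1] < penis_bounds_cm[2],
    penis_bounds_cm[1] > 0, operculum_sdlog >= 0
  )
  for (nm in names(noise)) {
    stopifnot(all(noise[[nm]] >= 0))
  }
  stopifnot(all(c("testis_sv", "penis", "ovary", "sex_allocation") %in%
                  names(coefficients)))
  penis_parent <- if (penis_sd_cm == 0) {
    c(mean = penis_mean_cm, sd = 0)
  } else {
    .truncnorm_parent(penis_mean_cm, penis_sd_cm,
                      penis_bounds_cm[1], penis_bounds_cm[2])
  }
  structure(
    list(
      n_shells = as.integer(n_shells),
      per_shell_range = per_shell_range,
      shell_radius_cm = shell_radius_cm,
      min_separation_cm = min_separation_cm,
      penis_mean_cm = penis_mean_cm,
      penis_sd_cm = penis_sd_cm,
      penis_bounds_cm = penis_bounds_cm,
      penis_parent = penis_parent,
      operculum_meanlog = operculum_meanlog,
      operculum_sdlog = operculum_sdlog,
      coefficients = coefficients,
      noise = noise,
      mode = mode,
      seed = as.integer(seed),
      study = study
    ),
    class = "generator_config"
  )
}

#' Draw penis lengths from the generator's truncated normal
#'
#' Inverse-CDF sampling from a normal truncated to the configured bounds,
#' moment-matched so the truncated draws themselves have the configured mean
#' and SD; with `penis_sd_cm = 0` every draw is the mean. Draws come from R's
#' current RNG stream: seed with `set.seed()` (or rely on the seed handling
#' inside [generate_population()]).
#'
#' @param n Number of draws.
#' @param config A [generator_config()].
#' @return Numeric vector of penis lengths, cm, all inside the bounds.
#' @export
sample_penis_length <- function(n, config = generator_config()) {
  if (config$penis_sd_cm == 0) return(rep(config$penis_mean_cm, n))
  parent <- config$penis_parent
  if (is.null(parent)) {
    parent <- .truncnorm_parent(config$penis_mean_cm, config$penis_sd_cm,
                                config$penis_bounds_cm[1],
                                config$penis_bounds_cm[2])
  }
  lo <- stats::pnorm(config$penis_bounds_cm[1], parent[["mean"]],
                     parent[["sd"]])
  hi <- stats::pnorm(config$penis_bounds_cm[2], parent[["mean"]],
                     parent[["sd"]])
  u <- stats::runif(n, lo, hi)
  stats::qnorm(u, parent[["mean"]], parent[["sd"]])
}

#' Draw operculum (body) weights
#'
#' Log-normal draws calibrated so the 1st-99th percentiles span the observed
#' operculum-weight range; only the range is observed, the log-normal shape
#' is a modeling choice.
#'
#' @inheritParams sample_penis_length
#' @return Numeric vector of operculum dry weights, mg.
#' @export
sample_operculum_weight <- function(n, config = generator_config()) {
  stats::rlnorm(n, config$operculum_meanlog, config$operculum_sdlog)
}

# positions uniform on a disc with minimum-separation rejection sampling
.sample_positions <- function(n, radius, min_sep, max_tries = 200L) {
  xs <- numeric(n)
  ys <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      r <- radius * sqrt(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi)
      x <- r * cos(th); y <- r * sin(th)
      if (i == 1 || all(sqrt((xs[seq_len(i - 1)] - x)^2 +
                               (ys[seq_len(i - 1)] - y)^2) >= min_sep)) {
        xs[i] <- x; ys[i] <- y; placed <- TRUE; break
      }
    }
    if (!placed) {
      stop("cannot place ", n, " individuals with minimum separation ",
           min_sep, " cm on a disc of radius ", radius,
           " cm; loosen the layout config")
    }
  }
  cbind(x = xs, y = ys)
}

#' Generate a synthetic population with ground truth
#'
#' Draws the layout (shell sizes, positions), morphology (penis lengths,
#' operculum weights), computes the TRUE mating group sizes by running the
#' mating-graph module on the generated geometry, and then generates the
#' responses from the configured linear mixed-model structure:
#' `response = intercept + b_m * MGSm + b_f * MGSf + b_body * body + shell
#' effect + residual`.
#'
#' In `organ_level` mode the three organ weights are generated from their own
#' coefficient sets and truncated below at 0.01 mg (truncations counted). In
#' `allocation_level` mode sex allocation is generated directly from its
#' coefficient set and clipped to \[0, 1\] (clips counted), the ovary and
#' penis come from their own models, and testis + seminal vesicle weight is
#' back-filled as `allocation / (1 - allocation) * ovary` so the recorded
#' organ weights reproduce the generated allocation exactly.
#'
#' @param config A [generator_config()]; `config$seed` fully determines the
#'   output.
#' @return List with `records` (a validated individuals `data.frame`) and
#'   `truth` (seed, mode, generating coefficients, noise levels, per-shell
#'   random effects, true MGS table, truncation/clip counts).
#' @export
generate_population <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  shells <- sprintf("s%03d", seq_len(config$n_shells))
  count_values <- seq(config$per_shell_range[1], config$per_shell_range[2])
  counts <- if (length(count_values) == 1) {
    rep(count_values, config$n_shells)
  } else {
    sample(count_values, config$n_shells, replace = TRUE)
  }
  pos <- vector("list", config$n_shells)
  for (k in seq_len(config$n_shells)) {
    pos[[k]] <- .sample_positions(counts[k], config$shell_radius_cm,
                                  config$min_separation_cm)
  }
  n <- sum(counts)
  shell_id <- rep(shells, counts)
  id <- sprintf("%s_b%02d", shell_id,
                unlist(lapply(counts, seq_len), use.names = FALSE))
  xy <- do.call(rbind, pos)
  records <- data.frame(
    id = id,
    shell_id = shell_id,
    x_cm = xy[, "x"],
    y_cm = xy[, "y"],
    operculum_radius_cm = 0,
    penis_length_cm = sample_penis_length(n, config),
    operculum_weight_mg = sample_operculum_weight(n, config),
    testis_sv_weight_mg = NA_real_,
    penis_weight_mg = NA_real_,
    ovary_weight_mg = NA_real_,
    stringsAsFactors = FALSE
  )

  graph <- build_mating_graph(records, config$study)
  mgs <- compute_mgs(graph)
  stopifnot(identical(mgs$id, records$id))

  X <- cbind(intercept = 1, mgs_m = mgs$mgs_m, mgs_f = mgs$mgs_f,
             body_weight = records$operculum_weight_mg)
  shell_idx <- match(shell_id, shells)
  shell_effects <- list()
  n_truncated <- 0L
  n_clipped <- 0L

  draw_response <- function(resp) {
    beta <- config$coefficients[[resp]]
    nz <- config$noise[[resp]]
    u <- stats::rnorm(config$n_shells, 0, nz[["shell_sd"]])
    shell_effects[[resp]] <<- stats::setNames(u, shells)
    drop(X %*% beta[colnames(X)]) + u[shell_idx] +
      stats::rnorm(n, 0, nz[["residual_sd"]])
  }

  if (config$mode == "organ_level") {
    for (resp in c("testis_sv", "penis", "ovary")) {
      y <- draw_response(resp)
      n_truncated <- n_truncated + sum(y < 0.01)
      y <- pmax(y, 0.01)
      col <- switch(resp, testis_sv = "testis_sv_weight_mg",
                    penis = "penis_weight_mg", ovary = "ovary_weight_mg")
      records[[col]] <- y
    }
  } else {
    alloc <- draw_response("sex_allocation")
    n_clipped <- sum(alloc < 0 | alloc > 1)
    alloc <- pmin(pmax(alloc, 0), 1)
    ovary <- draw_response("ovary")
    n_truncated <- n_truncated + sum(ovary < 0.01)
    ovary <- pmax(ovary, 0.01)
    penis <- draw_response("penis")
    n_truncated <- n_truncated + sum(penis < 0.01)
    penis <- pmax(penis, 0.01)
    a <- pmin(alloc, 1 - 1e-9)   # keep the back-fill ratio finite
    records$ovary_weight_mg <- ovary
    records$penis_weight_mg <- penis
    records$testis_sv_weight_mg <- a / (1 - a) * ovary
  }

  frac_bad <- (n_truncated + n_clipped) / n
  if (frac_bad > 0.01) {
    warning(sprintf(paste0("%.1f%% of generated responses were truncated or ",
                           "clipped; recovered coefficients may be biased"),
                    100 * frac_bad))
  }
  assert_valid_records(records)
  truth <- list(
    seed = config$seed,
    mode = config$mode,
    coefficients = config$coefficients,
    noise = config$noise,
    shell_effects = shell_effects,
    mgs = mgs,
    n_truncated = n_truncated,
    n_clipped = n_clipped
  )
  list(records = records, truth = truth)
}

#' Write the ground-truth sidecar of a generated population
#'
#' @param truth The `truth` element returned by [generate_population()].
#' @param path Output path (JSON).
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  # jsonlite serializes named atomic vectors as nameless arrays; promote them
  # to lists so coefficient and random-effect names survive
  truth$coefficients <- lapply(truth$coefficients, as.list)
  truth$shell_effects <- lapply(truth$shell_effects, as.list)
  truth$noise <- lapply(truth$noise, as.list)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}
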