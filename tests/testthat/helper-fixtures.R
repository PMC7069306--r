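# Fixtures built in code and an independent brute-force oracle for the
# reach graph. The oracle deliberately shares no code with the package's
# vectorized implementation: scalar arithmetic, explicit double loops.

# three barnacles on a line; reaches 4.55, 3.458, 5.46 => edges A->B, C->B
make_line_records <- function(organs = TRUE) {
  data.frame(
    id = c("A", "B", "C"),
    shell_id = "s1",
    x_cm = c(0, 4, 9),
    y_cm = 0,
    operculum_radius_cm = 0,
    penis_length_cm = c(2.5, 1.9, 3.0),
    operculum_weight_mg = c(500, 800, 1200),
    testis_sv_weight_mg = if (organs) c(50, 60, 70) else NA_real_,
    penis_weight_mg = if (organs) c(1.0, 1.2, 1.4) else NA_real_,
    ovary_weight_mg = if (organs) c(300, 400, 500) else NA_real_,
    stringsAsFactors = FALSE
  )
}

# focal individual that can reach 3 neighbours while 4 can reach it:
# MGSm = 4, MGSf = 5 including itself
make_focal_records <- function() {
  data.frame(
    id = c("focal", "n1", "n2", "n3", "n4"),
    shell_id = "s1",
    x_cm = c(0, 1, 0, -2, 5),
    y_cm = c(0, 0, 2, 0, 0),
    operculum_radius_cm = 0,
    penis_length_cm = c(2.0, 1.0, 1.2, 1.2, 3.0),
    operculum_weight_mg = 800,
    testis_sv_weight_mg = 80,
    penis_weight_mg = 1.0,
    ovary_weight_mg = 600,
    stringsAsFactors = FALSE
  )
}

# random multi-shell population with all organs present
random_records <- function(n_shells = 5, max_per_shell = 8, spread = 12) {
  rows <- lapply(seq_len(n_shells), function(s) {
    k <- sample(1:max_per_shell, 1)
    data.frame(
      id = sprintf("s%d_i%d", s, seq_len(k)),
      shell_id = sprintf("s%d", s),
      x_cm = stats::runif(k, 0, spread),
      y_cm = stats::runif(k, 0, spread),
      operculum_radius_cm = stats::runif(k, 0, 0.5),
      penis_length_cm = stats::runif(k, 1.67, 4.46),
      operculum_weight_mg = stats::runif(k, 245, 1807),
      testis_sv_weight_mg = stats::runif(k, 5, 228),
      penis_weight_mg = stats::runif(k, 0.33, 2.63),
      ovary_weight_mg = stats::runif(k, 63, 1950),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# O(n^2) brute-force edge enumeration, scalar arithmetic only
oracle_edges <- function(records, elongation = 1.82,
                         mode = c("center", "operculum_edge")) {
  mode <- match.arg(mode)
  out <- list()
  n <- nrow(records)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (records$shell_id[i] != records$shell_id[j]) next
      dx <- records$x_cm[i] - records$x_cm[j]
      dy <- records$y_cm[i] - records$y_cm[j]
      gap <- sqrt(dx * dx + dy * dy)
      if (mode == "operculum_edge") {
        gap <- gap - records$operculum_radius_cm[i] -
          records$operculum_radius_cm[j]
        if (gap < 0) gap <- 0
      }
      if (gap <= elongation * records$penis_length_cm[i]) {
        out[[length(out) + 1L]] <- c(records$id[i], records$id[j])
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(donor = character(), recipient = character(),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, out)
  data.frame(donor = m[, 1], recipient = m[, 2], stringsAsFactors = FALSE)
}

# brute-force degree counts from the oracle edges
oracle_mgs <- function(records, elongation = 1.82,
                       mode = c("center", "operculum_edge")) {
  ed <- oracle_edges(records, elongation, mode)
  mgs_m <- integer(nrow(records))
  mgs_f <- integer(nrow(records))
  for (i in seq_len(nrow(records))) {
    mgs_m[i] <- sum(ed$donor == records$id[i]) + 1L
    mgs_f[i] <- sum(ed$recipient == records$id[i]) + 1L
  }
  data.frame(id = records$id, mgs_m = mgs_m, mgs_f = mgs_f,
             stringsAsFactors = FALSE)
}

# canonical sorted "donor->recipient" strings for set comparison
edge_keys <- function(donor, recipient) {
  sort(paste(donor, recipient, sep = "->"))
}

# zero-noise generator config (small, truncation-free by construction)
zero_noise_config <- function(mode, seed = 101, n_shells = 25) {
  noise <- list(
    testis_sv = c(shell_sd = 0, residual_sd = 0),
    penis = c(shell_sd = 0, residual_sd = 0),
    ovary = c(shell_sd = 0, residual_sd = 0),
    sex_allocation = c(shell_sd = 0, residual_sd = 0)
  )
  generator_config(n_shells = n_shells, mode = mode, seed = seed,
                   noise = noise)
}
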