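# Independent oracles used across test files. These deliberately avoid the
# package's vectorised code paths: plain loops, naive filters.

# Exhaustive O(N^2) pairwise contact count over two atom tables.
brute_force_contacts <- function(a, b, cutoff, unit = "residues-of-b") {
  pairs <- 0L
  touched <- character()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                  (a$z[i] - b$z[j])^2)
      if (d <= cutoff) {
        pairs <- pairs + 1L
        touched <- c(touched, paste(b$chain_id[j], b$residue_seq[j],
                                    b$insertion_code[j]))
      }
    }
  }
  if (unit == "atom-pairs") pairs else length(unique(touched))
}

# Naive row-by-row selection filter.
naive_select <- function(model, chain = NULL, resno = NULL, resname = NULL,
                         aname = NULL, heavy = FALSE) {
  keep <- logical(nrow(model))
  for (i in seq_len(nrow(model))) {
    ok <- TRUE
    if (!is.null(chain)) ok <- ok && model$chain_id[i] %in% chain
    if (!is.null(resno)) ok <- ok && model$residue_seq[i] %in% resno
    if (!is.null(resname)) ok <- ok && model$residue_name[i] %in% resname
    if (!is.null(aname)) ok <- ok && model$atom_name[i] %in% aname
    if (heavy) ok <- ok && !model$element[i] %in% c("H", "D")
    keep[i] <- ok
  }
  model[keep, ]
}

# A random single-frame atom table: n atoms in a box, two chains, a few
# residues each, all carbon (heavy).
random_frame <- function(n = 60, box = 15) {
  tibble::tibble(
    frame = 1L, record = "ATOM", serial = seq_len(n),
    atom_name = paste0("C", seq_len(n) %% 4 + 1),
    residue_name = "ALA",
    chain_id = rep(c("A", "B"), length.out = n),
    residue_seq = as.integer(ceiling(seq_len(n) / 4)),
    insertion_code = "",
    x = stats::runif(n, 0, box), y = stats::runif(n, 0, box),
    z = stats::runif(n, 0, box),
    occupancy = 1, b_factor = 0, element = "C"
  )
}

# Seeded random rigid transform applied to a whole atom table.
rigid_transform_frame <- function(atoms) {
  q <- qr(matrix(stats::rnorm(9), 3, 3))
  rot <- qr.Q(q)
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  shift <- stats::rnorm(3, sd = 30)
  xyz <- cbind(atoms$x, atoms$y, atoms$z) %*% t(rot)
  atoms$x <- xyz[, 1] + shift[1]
  atoms$y <- xyz[, 2] + shift[2]
  atoms$z <- xyz[, 3] + shift[3]
  atoms
}

# Fixed-step Euler integration of dR/dt = kon*C*(Rmax - R) - koff*R with a
# buffer switch (C -> 0) at t_switch; the numerical oracle for the analytic
# sensorgram solution.
euler_sensorgram <- function(times, conc, kon, koff, rmax, t_switch,
                             dt = 0.005) {
  grid <- seq(0, max(times), by = dt)
  r <- numeric(length(grid))
  for (i in seq_along(grid)[-1]) {
    cc <- if (grid[i - 1] < t_switch) conc else 0
    dr <- kon * cc * (rmax - r[i - 1]) - koff * r[i - 1]
    r[i] <- r[i - 1] + dt * dr
  }
  stats::approx(grid, r, xout = times)$y
}
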