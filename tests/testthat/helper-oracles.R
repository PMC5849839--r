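# Independent oracles and fixture builders used across the suite.

# literal transcription of the convolution double sum, O(N^2 M^2); the slow
# reference both fast routes are checked against
naive_conv_same <- function(f, k) {
  nf <- dim(f); nk <- dim(k)
  half <- (nk - 1L) %/% 2L
  out <- matrix(0, nf[1], nf[2])
  for (x in seq_len(nf[1])) for (y in seq_len(nf[2])) {
    acc <- 0
    for (n1 in seq_len(nk[1])) for (n2 in seq_len(nk[2])) {
      i <- x - (n1 - 1L - half[1])
      j <- y - (n2 - 1L - half[2])
      if (i >= 1 && i <= nf[1] && j >= 1 && j <= nf[2]) {
        acc <- acc + k[n1, n2] * f[i, j]
      }
    }
    out[x, y] <- acc
  }
  out
}

# brute-force count of integer lattice points strictly inside a circle of
# radius r_px centered on a lattice point
lattice_count_in_circle <- function(r_px) {
  lim <- ceiling(r_px)
  g <- expand.grid(i = -lim:lim, j = -lim:lim)
  sum(g$i^2 + g$j^2 < r_px^2)
}

# an aperture_mask around a hand-built 0/1 matrix, bypassing rasterization
make_mask <- function(values, resolution_mm = 1, origin = c(x_cm = 0, y_cm = 0),
                      label = "manual") {
  storage.mode(values) <- "integer"
  structure(
    list(values = values, resolution_mm = resolution_mm,
         origin = c(x_cm = unname(origin[1]), y_cm = unname(origin[2])),
         label = label),
    class = "aperture_mask"
  )
}

# random strictly monotone OF curve on 1..6 cm (seeded)
random_monotone_curve <- function(seed) {
  withr::with_seed(seed, {
    plateau <- runif(1, 0.6, 1.1)
    steps <- sort(runif(6, 0.01, 1))
    of <- plateau * steps / max(steps)
    of_curve(tibble::tibble(radius_cm = 1:6, output_factor = of))
  })
}

# random 0/1 mask with a guaranteed blocked margin
random_padded_mask <- function(n, margin, p_open = 0.4, seed = 1) {
  v <- matrix(0L, n, n)
  core <- (margin + 1):(n - margin)
  withr::with_seed(seed, {
    v[core, core] <- matrix(rbinom(length(core)^2, 1, p_open),
                            length(core), length(core))
  })
  make_mask(v)
}
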