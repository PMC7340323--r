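## shared fixtures built in code

ref_optics <- function(...) optical_system(...)
ref_camera <- function(...) camera_model(...)

quiet_camera <- function(...) {
  camera_model(read_noise_e = 0, dark_rate_e_s = 0, bias_adu = 0, ...)
}

## toy event image with given counts matrix
toy_image <- function(counts, pitch = 17.7778) {
  event_image(counts, pitch)
}

## sampled circular Gaussian on an n x n grid (pitch 1), closed form
gaussian_counts <- function(n = 41, sigma = 10, amp = 100, offset = 0,
                            x0 = 0, y0 = 0) {
  ctr <- seq_len(n) - (n + 1) / 2
  g <- outer(ctr - y0, ctr - x0,
             function(y, x) amp * exp(-(x^2 + y^2) / (2 * sigma^2)))
  round(g + offset)
}

## independent recursive flood fill (8-connectivity), used as the oracle
## against the package's component labelling
flood_fill_labels <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  cur <- 0L
  for (j in seq_len(nx)) for (i in seq_len(ny)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    lab[i, j] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && ii <= ny && jj >= 1 && jj <= nx &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          stack[[length(stack) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

## canonical partition of a labelled matrix: sorted list of sorted pixel
## index sets, for comparing two labelling routes
label_partition <- function(lab) {
  sets <- split(which(lab != 0L), lab[lab != 0L])
  sets <- lapply(sets, sort)
  sets[order(vapply(sets, min, numeric(1)))]
}
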