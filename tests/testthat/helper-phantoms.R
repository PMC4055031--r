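# Shared fixtures: phantoms are deterministic given their spec, so a small
# cache avoids regenerating the same scene across tests.
.phantom_cache <- new.env(parent = emptyenv())

cached_phantom <- function(...) {
  spec <- phantom_spec(...)
  key <- paste(unlist(spec), collapse = "|")
  if (is.null(.phantom_cache[[key]]))
    .phantom_cache[[key]] <- make_phantom(spec)
  .phantom_cache[[key]]
}

# brute-force 2D convolution with a separable kernel and reflect padding;
# independent oracle for the separable filtering code
brute_conv2 <- function(img, krow, kcol) {
  h <- nrow(img)
  w <- ncol(img)
  rr <- (length(krow) - 1L) %/% 2L
  rc <- (length(kcol) - 1L) %/% 2L
  refl <- function(i, n) {
    p <- 2L * n - 2L
    i <- (i - 1L) %% p
    ifelse(i >= n, p - i, i) + 1L
  }
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0
    for (a in seq_along(krow)) for (b in seq_along(kcol)) {
      si <- refl(i - (a - rr - 1L), h)
      sj <- refl(j - (b - rc - 1L), w)
      acc <- acc + krow[a] * kcol[b] * img[si, sj]
    }
    out[i, j] <- acc
  }
  out
}

# circular absolute angular difference in degrees
ang_diff <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}
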