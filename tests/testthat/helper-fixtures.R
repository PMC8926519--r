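# Small deterministic fixtures shared across the suite.

tinyPhantomConfig <- function(...) {
  deskPhantomConfig(...)
}

# lightweight hand-built sample (no generator): a small centered square
# tumor with consistent labels
squareSample <- function(n = 32L, lo = 14L, hi = 18L, id = "S0001_I01") {
  normal <- matrix(0L, n, n)
  normal[lo:hi, lo:hi] <- 1L
  boundary <- boundaryFromMask(normal, 2L)
  img <- 0.4 + 0.08 * normal
  elmseg:::imageSample(img, normal, boundary, "present", id)
}

# minimal stand-in samples for split/accounting tests (tiny rasters)
dummySample <- function(subject, image) {
  normal <- matrix(0L, 8L, 8L)
  normal[4L, 4L] <- 1L
  boundary <- normal
  elmseg:::imageSample(matrix(0.5, 8L, 8L), normal, boundary, "present",
                       sprintf("S%04d_I%02d", subject, image))
}

dummyDataset <- function(nSubjects, perSubject) {
  out <- list()
  for (s in seq_len(nSubjects)) {
    for (i in seq_len(perSubject)) {
      out[[length(out) + 1L]] <- dummySample(s, i)
    }
  }
  out
}
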