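# quick event-table constructors used across test files

make_events <- function(values, channel = "GFP", role = "experimental",
                        id = "s", ...) {
  ch <- list()
  ch[[channel]] <- values
  event_table(as.data.frame(ch), id, role = role, ...)
}

make_events2 <- function(x, y, chx = "Ki67", chy = "aCasp3",
                         id = "s", ...) {
  ch <- list()
  ch[[chx]] <- x
  ch[[chy]] <- y
  event_table(as.data.frame(ch), id, ...)
}

# brute-force Overton oracle: explicit per-bin loop, independent of the
# package's vectorized implementation
overton_brute <- function(xs, xc, breaks) {
  nb <- length(breaks) - 1
  hs <- hc <- numeric(nb)
  for (j in seq_len(nb)) {
    lo <- breaks[j]; hi <- breaks[j + 1]
    if (j < nb) {
      hs[j] <- sum(xs >= lo & xs < hi) / length(xs)
      hc[j] <- sum(xc >= lo & xc < hi) / length(xc)
    } else {
      hs[j] <- sum(xs >= lo & xs <= hi) / length(xs)
      hc[j] <- sum(xc >= lo & xc <= hi) / length(xc)
    }
  }
  d <- hs - hc
  cum <- numeric(nb)
  run <- 0
  for (j in seq_len(nb)) { run <- run + d[j]; cum[j] <- run }
  jmin <- 1
  for (j in seq_len(nb)) if (cum[j] < cum[jmin]) jmin <- j
  tot <- 0
  if (jmin < nb) for (j in (jmin + 1):nb) if (d[j] > 0) tot <- tot + d[j]
  min(max(100 * tot, 0), 100)
}

# brute-force maximum-difference oracle: scan every pooled event value
maxdiff_brute <- function(xs, xc) {
  cand <- sort(unique(c(xs, xc)))
  best_v <- cand[1]; best_d <- -Inf
  for (v in cand) {
    d <- mean(xc <= v) - mean(xs <= v)
    if (d > best_d) { best_d <- d; best_v <- v }
  }
  list(threshold = best_v, diff = best_d)
}
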