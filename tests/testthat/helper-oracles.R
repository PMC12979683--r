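# nested-loop focal-sum oracle shared by the raster and acceptance suites
bruteFocalSum <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(NA_integer_, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    if (is.na(m[i, j]) || m[i, j] != 1) next
    s <- 0L
    for (dx in -4:3) for (dy in -4:3) {
      ii <- i + dx; jj <- j + dy
      if (ii >= 1 && ii <= nx && jj >= 1 && jj <= ny &&
          !is.na(m[ii, jj]) && m[ii, jj] == 1) s <- s + 1L
    }
    out[i, j] <- s
  }
  out
}
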