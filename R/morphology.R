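# Small dimension-agnostic binary morphology helpers (2-D/3-D) used by the
# head segmentation: zero-padded axis shifts, cross-shaped dilation/erosion,
# closing, and connected components by frontier growth.

shift_arr <- function(arr, ax, by) {
  d <- dim(arr)
  n <- d[ax]
  out <- array(0, d)
  if (abs(by) >= n) return(out)
  src <- if (by > 0) seq_len(n - by) else seq(1 - by, n)
  dst <- if (by > 0) seq(1 + by, n) else seq_len(n + by)
  idx_src <- rep(list(quote(expr = )), length(d))
  idx_dst <- idx_src
  idx_src[[ax]] <- src
  idx_dst[[ax]] <- dst
  out <- do.call(`[<-`, c(list(out), idx_dst,
                          list(do.call(`[`, c(list(arr), idx_src)))))
  out
}

dilate1 <- function(mask) {
  out <- mask
  for (ax in seq_along(dim(mask)))
    out <- out | shift_arr(mask, ax, 1) | shift_arr(mask, ax, -1)
  out
}

erode1 <- function(mask) {
  out <- mask
  for (ax in seq_along(dim(mask)))
    out <- out & shift_arr(mask, ax, 1) & shift_arr(mask, ax, -1)
  out
}

morph_close <- function(mask, iter = 2L) {
  m <- mask
  for (i in seq_len(iter)) m <- dilate1(m)
  for (i in seq_len(iter)) m <- erode1(m)
  m
}

# largest 4-/6-connected component of a logical array
largest_component <- function(mask) {
  remaining <- mask
  best <- NULL
  best_n <- 0L
  while (any(remaining)) {
    seed <- array(FALSE, dim(mask))
    seed[which(remaining)[1]] <- TRUE
    comp <- seed
    repeat {
      grown <- dilate1(comp) & remaining
      if (sum(grown) == sum(comp)) break
      comp <- grown
    }
    n <- sum(comp)
    if (n > best_n) { best <- comp; best_n <- n }
    remaining <- remaining & !comp
  }
  if (is.null(best)) array(FALSE, dim(mask)) else best
}
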