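# Independent oracles and small fixture builders, written from the
# definitions rather than through the package's code paths.

# Correlation of one placement by direct double-loop summation: mean-center
# each patch, divide by the root of its centered sum of squares, accumulate
# the products pixel by pixel.
brute_ncc <- function(image, template, x, y) {
  H <- nrow(template); W <- ncol(template)
  t_mean <- sum(template) / (W * H)
  win <- image[y:(y + H - 1), x:(x + W - 1)]
  w_mean <- sum(win) / (W * H)
  et <- 0; ew <- 0; num <- 0
  for (i in seq_len(H)) for (j in seq_len(W)) {
    td <- template[i, j] - t_mean
    wd <- win[i, j] - w_mean
    et <- et + td * td
    ew <- ew + wd * wd
    num <- num + td * wd
  }
  if (et == 0 || ew == 0) return(NA_real_)
  num / (sqrt(et) * sqrt(ew))
}

brute_match_map <- function(image, template) {
  H <- nrow(template); W <- ncol(template)
  out <- matrix(NA_real_, nrow(image) - H + 1, ncol(image) - W + 1)
  for (y in seq_len(nrow(out))) for (x in seq_len(ncol(out)))
    out[y, x] <- brute_ncc(image, template, x, y)
  out
}

# Maximum number of one-to-one detection/truth matches within `tol`,
# by exhaustive recursive assignment (small instances only).
brute_max_matches <- function(det_xy, truth_xy, tol) {
  nd <- nrow(det_xy); nt <- nrow(truth_xy)
  if (!nd || !nt) return(0L)
  ok <- outer(seq_len(nd), seq_len(nt), function(i, j)
    sqrt((det_xy[i, 1] - truth_xy[j, 1])^2 +
         (det_xy[i, 2] - truth_xy[j, 2])^2) <= tol)
  best <- 0L
  recurse <- function(j, used, count) {
    if (j > nt) { best <<- max(best, count); return(invisible()) }
    recurse(j + 1L, used, count)                    # leave truth j unmatched
    for (i in which(ok[, j] & !used)) {
      used[i] <- TRUE
      recurse(j + 1L, used, count + 1L)
      used[i] <- FALSE
    }
  }
  recurse(1L, logical(nd), 0L)
  best
}

# Toy bright-blob template and an embedding helper for fast detection tests
# that do not need the full-size insect generator.
toy_template <- function() {
  tmpl <- matrix(10, 12, 16)
  ys <- row(tmpl) - 6.5; xs <- col(tmpl) - 8.5
  tmpl[(xs / 6)^2 + (ys / 4)^2 <= 1] <- 200
  tmpl
}

# Paste a patch with its top-left at (x, y), clipping at the borders.
embed_patch <- function(image, patch, x, y) {
  for (i in seq_len(nrow(patch))) for (j in seq_len(ncol(patch))) {
    r <- y + i - 1; c <- x + j - 1
    if (r >= 1 && r <= nrow(image) && c >= 1 && c <= ncol(image))
      image[r, c] <- patch[i, j]
  }
  image
}

disk_mask <- function(radius, pad = 3L) {
  n <- 2L * (radius + pad) + 1L
  ctr <- radius + pad + 1L
  m <- matrix(0L, n, n)
  m[(row(m) - ctr)^2 + (col(m) - ctr)^2 <= radius^2] <- 1L
  m
}
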