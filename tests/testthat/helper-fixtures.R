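# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, fn) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- fn()
  .fixtures[[name]]
}

# compact phantom spec used by most tests: 36^3 at 4 mm
small_spec <- function(...) {
  phantom_spec(grid_shape = c(36, 36, 36), spacing_mm = c(4, 4, 4), ...)
}

small_template <- function() {
  get_fixture("small_template", function() make_template(small_spec()))
}

small_subject <- function() {
  get_fixture("small_subject", function()
    sample_subject(small_template(), small_spec(), seed = 7))
}

# tiny random label array over the given codes
random_labels <- function(dims, codes = 0:3) {
  array(sample(codes, prod(dims), replace = TRUE), dim = dims)
}

# ---- independent brute-force oracles ---------------------------------------

# Dice from explicit confusion counts (no reuse of package internals)
oracle_dice <- function(pred, truth, class) {
  p <- as.vector(pred) == class
  t <- as.vector(truth) == class
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t)
  if (2 * tp + fp + fn == 0) return(1.0)
  2 * tp / (2 * tp + fp + fn)
}

oracle_vs <- function(pred, truth, class) {
  vx <- sum(pred == class); vy <- sum(truth == class)
  if (vx + vy == 0) return(1.0)
  1 - abs(vx - vy) / (vx + vy)
}

# directed HD95 by exhaustive pairwise distances
oracle_hd95 <- function(pred, truth, class, spacing) {
  pi <- which(array(pred, dim = dim(pred)) == class, arr.ind = TRUE)
  ti <- which(array(truth, dim = dim(truth)) == class, arr.ind = TRUE)
  if (nrow(pi) == 0 || nrow(ti) == 0) return(NaN)
  pm <- sweep(pi, 2, spacing, "*")
  tm <- sweep(ti, 2, spacing, "*")
  mins <- apply(pm, 1, function(v)
    sqrt(min(colSums((t(tm) - v)^2))))
  unname(quantile(mins, 0.95, type = 7))
}

oracle_intra_acc <- function(pred, mask, ok_codes) {
  if (sum(mask) == 0) return(NA_real_)
  sum(pred[mask] %in% ok_codes) / sum(mask)
}
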