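# Shared tiny fixtures, built once per test run and memoized.

.ft_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .ft_cache)) assign(key, force(expr), .ft_cache)
  get(key, .ft_cache)
}

# a small synthetic section + ground truth (default study profile)
tiny_section <- function() {
  cached("tiny_section", generate_section(synth_config(), seed = 42))
}

# a minimal section object from raw pixels
section_from <- function(img, um_per_px = 20) {
  ft_section(img, um_per_px = um_per_px)
}

# a tiny model that trains in seconds
tiny_model <- function(patch = 64L, seed = 7L) {
  build_model(model_config(depth = 3L, base_channels = 8L,
                           fc_sizes = c(64L, 32L), patch_size = patch,
                           seed = seed))
}

# brute-force focal loss: direct per-element transcription, no vectorization
focal_brute <- function(p, y, alpha = 0.25, gamma = 2,
                        alpha_weighting = TRUE, eps = 1e-7) {
  tot <- 0
  for (i in seq_along(p)) {
    pt <- if (y[i] == 1) p[i] else 1 - p[i]
    pt <- min(max(pt, eps), 1 - eps)
    at <- if (!alpha_weighting) 1 else if (y[i] == 1) alpha else 1 - alpha
    tot <- tot + (-at * (1 - pt)^gamma * log(pt))
  }
  tot / length(p)
}

# brute-force NT-Xent: direct transcription of the per-pair definition
contrastive_brute <- function(emb, tau = 0.5) {
  m <- nrow(emb)
  cosim <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  total <- 0
  for (i in seq_len(m)) {
    j <- if (i %% 2 == 1) i + 1 else i - 1
    num <- exp(cosim(emb[i, ], emb[j, ]) / tau)
    den <- 0
    for (k in seq_len(m)) {
      if (k != i) den <- den + exp(cosim(emb[i, ], emb[k, ]) / tau)
    }
    total <- total - log(num / den)
  }
  total / m
}

# hand/textbook one-way ANOVA F statistic
anova_brute <- function(values, groups) {
  g <- split(values, groups)
  k <- length(g)
  n <- length(values)
  gm <- mean(values)
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - gm)^2, numeric(1)))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
  (ssb / (k - 1)) / (ssw / (n - k))
}

# label map with rectangular regions of given pixel counts (row-stacked)
rect_label_map <- function(H, W, widths, heights, gap = 4L, origin = c(10L, 10L)) {
  lab <- matrix(0L, H, W)
  r <- origin[1]
  for (i in seq_along(widths)) {
    lab[r:(r + heights[i] - 1), origin[2]:(origin[2] + widths[i] - 1)] <- i
    r <- r + heights[i] + gap
  }
  lab
}
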