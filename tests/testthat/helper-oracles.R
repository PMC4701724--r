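# Independent brute-force oracles. These re-derive the statistics from
# first principles (rank enumeration, pairwise concordance counting,
# eigendecomposition of the correlation matrix) and are deliberately kept
# free of the code paths they check.

# Pearson correlation written out by hand
cor_hand <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# average ranks by counting, ties get the mean of the ranks they span
ranks_by_counting <- function(v) {
  vapply(seq_along(v), function(i) {
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
  }, numeric(1))
}

spearman_oracle <- function(x, y) {
  cor_hand(ranks_by_counting(x), ranks_by_counting(y))
}

# Kendall tau-b by explicit enumeration of all C(n,2) pairs of pairs
kendall_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- tied_x <- tied_y <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
      if (dx == 0) tied_x <- tied_x + 1
      if (dy == 0) tied_y <- tied_y + 1
      if (dx != 0 && dy != 0) {
        if (dx == dy) conc <- conc + 1 else disc <- disc + 1
      }
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tied_x) * (n0 - tied_y))
}

# PCA of the correlation matrix by eigendecomposition
pca_oracle <- function(m) {
  z <- scale(m, center = TRUE, scale = TRUE)
  ev <- eigen(stats::cor(m), symmetric = TRUE)
  list(loadings = ev$vectors, scores = z %*% ev$vectors,
       variance_explained = ev$values / sum(ev$values))
}

# align component signs of `got` to `want` before comparison
align_signs <- function(got, want) {
  for (j in seq_len(ncol(got))) {
    if (sum(got[, j] * want[, j]) < 0) got[, j] <- -got[, j]
  }
  got
}

# quick builders -------------------------------------------------------

make_series <- function(values, years = seq(1964, length.out = length(values)),
                        id = "s1", category = "biomass", source = "observed") {
  eco_series(id, category, source, years, values)
}

make_pair <- function(obs, mod, years = seq_along(obs)) {
  structure(list(series_id = "pair", category = "biomass",
                 years = as.integer(years), obs = as.numeric(obs),
                 mod = as.numeric(mod), n = length(obs)),
            class = "eco_pair")
}

# a small deterministic ecosystem dataset with hand-set numbers:
# one demersal fish, one pelagic fish, one benthos, one whale,
# constant-by-default series so indicator arithmetic can be done by hand
make_mini_dataset <- function(years = 2000:2009,
                              dem_bio = 10, pel_bio = 5, ben_bio = 20,
                              whale_bio = 2,
                              dem_catch = 3, pel_catch = 2,
                              pp = 100,
                              dem_tl = 4.0, pel_tl = 3.0,
                              dem_price = 10, pel_price = 1) {
  const <- function(v) if (length(v) == 1L) rep(v, length(years)) else v
  md <- data.frame(
    group_id = c("DEM", "PEL", "BEN", "WHL"),
    name = c("demersal", "pelagic", "benthos", "whale"),
    guild = c("demersal_fish", "pelagic_fish", "benthos", "mammal_whale"),
    is_fish = c(TRUE, TRUE, FALSE, FALSE),
    is_commercial = c(TRUE, TRUE, FALSE, FALSE),
    is_tep = c(FALSE, FALSE, FALSE, TRUE),
    trophic_level = c(dem_tl, pel_tl, 2.5, 3.8),
    price_per_ton = c(dem_price, pel_price, 0, 0),
    stringsAsFactors = FALSE)
  bio_one <- function(id, v, src) data.frame(
    group_id = id, source = src, year = years, value = const(v),
    stringsAsFactors = FALSE)
  bio <- rbind(bio_one("DEM", dem_bio, "observed"),
               bio_one("PEL", pel_bio, "observed"),
               bio_one("BEN", ben_bio, "observed"),
               bio_one("WHL", whale_bio, "observed"),
               bio_one("DEM", dem_bio, "modeled"),
               bio_one("PEL", pel_bio, "modeled"),
               bio_one("BEN", ben_bio, "modeled"),
               bio_one("WHL", whale_bio, "modeled"))
  lan <- rbind(bio_one("DEM", dem_catch, "observed"),
               bio_one("PEL", pel_catch, "observed"),
               bio_one("DEM", dem_catch, "modeled"),
               bio_one("PEL", pel_catch, "modeled"))
  ppdf <- rbind(data.frame(source = "observed", year = years,
                           value = const(pp), stringsAsFactors = FALSE),
                data.frame(source = "modeled", year = years,
                           value = const(pp), stringsAsFactors = FALSE))
  ecosystem_dataset(biomass = bio, landings = lan,
                    primary_production = ppdf, metadata = md)
}
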