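# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and lm/cor) so that agreement is informative.

# simple-regression statistics straight from the normal equations
ols_oracle <- function(x, y) {
  n <- length(x)
  xb <- sum(x) / n
  yb <- sum(y) / n
  sxx <- sum((x - xb)^2)
  sxy <- sum((x - xb) * (y - yb))
  syy <- sum((y - yb)^2)
  slope <- sxy / sxx
  intercept <- yb - slope * xb
  sse <- sum((y - (intercept + slope * x))^2)
  r2 <- if (syy == 0) 0 else 1 - sse / syy
  list(
    slope = slope, intercept = intercept, r2 = r2,
    adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 2),
    sigma = sqrt(sse / (n - 2)),
    f_stat = if (r2 < 1) r2 / (1 - r2) * (n - 2) else Inf,
    n = n
  )
}

# average ranks by pairwise counting (handles ties the standard way)
rank_oracle <- function(v) {
  vapply(seq_along(v), function(i) {
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
  }, numeric(1))
}

pearson_oracle <- function(x, y) {
  xb <- mean(x)
  yb <- mean(y)
  sum((x - xb) * (y - yb)) / sqrt(sum((x - xb)^2) * sum((y - yb)^2))
}

spearman_oracle <- function(x, y) {
  pearson_oracle(rank_oracle(x), rank_oracle(y))
}

# per-year unique-author counts by materialising the name set, written
# without name_key()/census()
census_oracle <- function(rs) {
  long <- authors_long(rs)
  long <- long[!is.na(long$year), ]
  norm <- function(s) {
    tolower(gsub("\\s+", " ", trimws(stringi::stri_trans_nfc(s))))
  }
  key <- paste(norm(long$last), norm(long$first), sep = "\r")
  counts <- tapply(key, long$year, function(k) length(unique(k)))
  data.frame(year = as.integer(names(counts)), unique_authors = as.integer(counts))
}

# record-set builders -------------------------------------------------------

make_authors <- function(...) {
  pairs <- list(...)
  data.frame(
    last = vapply(pairs, `[`, "", 1),
    first = vapply(pairs, `[`, "", 2)
  )
}

# ten hand-built records with known eligibility outcomes:
#   eligible: 1, 2, 4, 7, 8, 10 (record 4 loses its initials-only coauthor)
#   dropped:  3 (no year), 5 (lone author lacks first name), 6 (no authors),
#             9 (no year and no usable author)
ten_record_fixture <- function() {
  record_set(
    pmid = as.character(1:10),
    year = c(2001L, 2002L, NA, 2003L, 2004L, 2005L, 2001L, 2001L, NA, 2002L),
    authors = list(
      make_authors(c("Alvarez", "Nadia")),
      make_authors(c("Brandt", "Otto"), c("Cole", "Mira")),
      make_authors(c("Dietrich", "Sven")),
      make_authors(c("Eng", "Lian"), c("Fox", "")),
      make_authors(c("Grau", "")),
      data.frame(last = character(), first = character()),
      make_authors(c("Alvarez", "Nadia"), c("Brandt", "Otto")),
      make_authors(c("Hooper", "Zed")),
      make_authors(c("Iqbal", "")),
      make_authors(c("Alvarez", "NADIA"))
    ),
    provenance = "ten-record fixture"
  )
}

small_corpus_spec <- function(years = 2001:2008, rate = 0.1, initial = 25, ...) {
  corpus_spec(years, growth_exponential(rate = rate, initial = initial), ...)
}
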