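# Shared, lazily built simulation fixtures. The default ten-subject cohort is
# expensive enough (~10 s) that tests reuse one copy.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, expr, envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

default_cohort_features <- function() {
  cached("feats_seed42", featurize_cohort(generate_cohort(10, 42)))
}

# 4 subjects x 150 s: enough for LOSO round trips without the full cost
small_protocol <- function() {
  default_protocol(c(quiet_sit = 30, eat_sit = 30, talk = 30,
                     eat_walk = 30, walk = 30))
}

small_cohort <- function() {
  cached("small_cohort_seed7", generate_cohort(4, 7, small_protocol()))
}

small_cohort_features <- function() {
  cached("small_feats_seed7", featurize_cohort(small_cohort()))
}

default_recording <- function() {
  cached("rec_s01_seed42", generate_subject(draw_profiles(2, 42)[[1]]))
}

# Loop-based reference implementations of the four epoch features, kept
# independent of the vectorized package code.
oracle_range <- function(x) {
  mx <- x[1]; mn <- x[1]
  for (v in x) { if (v > mx) mx <- v; if (v < mn) mn <- v }
  mx - mn
}
oracle_std <- function(x) {
  m <- 0
  for (v in x) m <- m + v
  m <- m / length(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  sqrt(s / (length(x) - 1))
}
oracle_energy <- function(x) {
  s <- 0
  for (v in x) s <- s + v * v
  s
}
oracle_wl <- function(x) {
  s <- 0
  for (k in 2:length(x)) s <- s + abs(x[k] - x[k - 1])
  s
}

# Mann-Whitney pair-counting AUC: P(score+ > score-) + 0.5 P(equal)
oracle_auc <- function(labels, scores) {
  sp <- scores[labels == 1]
  sn <- scores[labels != 1]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}
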