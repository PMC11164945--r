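# Shared fixtures, all generated in code at test time.

# a small two-site cohort with images at reduced resolution
mini_cohort <- function(counts_private = c(3L, 3L, 3L, 3L),
                        counts_public = c(3L, 3L, 3L, 3L),
                        images_per_patient = 2L, px = 32L, seed = 1L) {
  cfg <- cohort_config(
    "tiny",
    per_site_grade_counts = list(private_like = counts_private,
                                 public_like = counts_public),
    images_per_patient = images_per_patient,
    image_size = list(private_like = c(px, px), public_like = c(px, px)),
    seed = seed)
  cohort <- generate_cohort(cfg)
  list(config = cfg, cohort = cohort,
       images = generate_images(cohort, cfg))
}

# a synthetic patient table without images, for partition arithmetic
toy_pool <- function(n_s0, n_s1, site = "private_like") {
  n <- n_s0 + n_s1
  data.frame(
    patient_id = sprintf("p%04d", seq_len(n)),
    site = site,
    grade = c(rep(0L, n_s0), rep(2L, n_s1)),
    binary_class = c(rep("S0", n_s0), rep("S1plus", n_s1)),
    sex = "F", age = 50, bmi = 30,
    stringsAsFactors = FALSE)
}

# the default-conditions training pool (two-center study cohort, balanced
# 10 + 10 test split): 42 S0 / 146 S1plus
default_split <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      cfg <- cohort_config("tiny")
      cohort <- generate_cohort(cfg)
      memo <<- make_test_split(cohort, 10L, seed = 1L)
    }
    memo
  }
})

# scalar weight vectors for server-rule algebra
wv1 <- function(x) list(w = array(x, dim = c(1, 1)))

# brute-force O(n^2) AUC by pair counting (independent oracle)
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (x in pos) tot <- tot + sum(x > neg) + 0.5 * sum(x == neg)
  tot / (length(pos) * length(neg))
}

# midrank AUC used inside the bootstrap oracle
auc_rank <- function(s, y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  r <- rank(s)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# tiny federated fixture: 8 patients, 16x16 images, 3-round runs in seconds
fed_fixture <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      mc <- mini_cohort(counts_private = c(2L, 1L, 1L, 2L),
                        counts_public = c(2L, 0L, 2L, 0L),
                        images_per_patient = 2L, px = 16L, seed = 4L)
      memo <<- mc
    }
    memo
  }
})

fed_fixture_config <- function(...) {
  train_config(arch = "tiny", input_size = 16L, batch_size = 4L,
               learning_rate = 1e-3, ...)
}
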