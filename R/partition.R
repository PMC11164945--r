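## Non-IID partitioning of a patient pool into simulated federated sites.
## All strategies return a list of site partitions and guarantee an exact
## multiset partition of the input pool (asserted on every call). Patients
## are atomic: images never split across sites.

CLASSES <- c("S0", "S1plus")

# Hamilton / largest-remainder apportionment of `total` units to shares
# `p` (non-negative, summed to 1 internally). Conserves the total exactly;
# ties broken toward lower indices.
apportion_lr <- function(p, total) {
  stopifnot(all(p >= 0), total >= 0)
  if (sum(p) == 0) p <- rep(1, length(p))
  q <- p / sum(p) * total
  base <- floor(q)
  left <- round(total - sum(base))
  if (left > 0) {
    rem <- q - base
    ord <- order(-rem, seq_along(rem))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

rdirichlet1 <- function(n, beta) {
  g <- rgamma(n, shape = beta, rate = 1)
  if (sum(g) == 0) g <- rep(1, n)
  g / sum(g)
}

new_site_partition <- function(site_id, patients) {
  counts <- vapply(CLASSES, function(cl)
    sum(patients$binary_class == cl), integer(1))
  structure(list(site_id = site_id, patients = patients,
                 class_counts = counts, n = nrow(patients)),
            class = "site_partition")
}

#' @export
print.site_partition <- function(x, ...) {
  cat("Site", x$site_id, "-", x$n, "patients (",
      paste(sprintf("%s: %d", names(x$class_counts), x$class_counts),
            collapse = ", "), ")\n")
  invisible(x)
}

assert_conservation <- function(sites, pool) {
  got <- sort(unlist(lapply(sites, function(s) s$patients$patient_id)))
  want <- sort(pool$patient_id)
  if (!identical(as.character(got), as.character(want)))
    stop("internal error: partition does not conserve the pool")
  sites
}

pool_rows <- function(pool, ids) pool[match(ids, pool$patient_id), , drop = FALSE]

#' Distribution-based class skew: Dirichlet allocation per class
#'
#' For each binary class independently, draws site shares from a symmetric
#' Dirichlet with concentration `beta` and allocates that class's patients
#' to sites by largest-remainder rounding of the drawn shares. Small `beta`
#' yields extreme class imbalance across sites; large `beta` approaches a
#' uniform split.
#'
#' @param pool training-pool data.frame (rows are patients).
#' @param n_sites number of simulated sites.
#' @param beta Dirichlet concentration, > 0.
#' @param seed integer RNG seed.
#' @return list of site partitions.
#' @export
dirichlet_class_partition <- function(pool, n_sites, beta, seed = 1L) {
  if (nrow(pool) == 0) stop("pool is empty")
  if (beta <= 0) stop("beta must be > 0")
  with_seed(derive_seed(seed, 11L), {
    assign <- setNames(vector("list", n_sites), seq_len(n_sites))
    for (cl in CLASSES) {
      ids <- pool$patient_id[pool$binary_class == cl]
      if (!length(ids)) next
      ids <- sample(ids)
      counts <- apportion_lr(rdirichlet1(n_sites, beta), length(ids))
      stops <- cumsum(counts)
      starts <- c(1L, head(stops, -1L) + 1L)
      for (i in seq_len(n_sites))
        if (counts[i] > 0)
          assign[[i]] <- c(assign[[i]], ids[starts[i]:stops[i]])
    }
    sites <- lapply(seq_len(n_sites), function(i)
      new_site_partition(i, pool_rows(pool, assign[[i]])))
    assert_conservation(sites, pool)
  })
}

#' Quantity-based class skew: each site owns a fixed set of classes
#'
#' Classes are dealt to sites round-robin until every site owns
#' `classes_per_site` classes; each class's patients are then split equally
#' among the sites owning it (remainders go to the lowest site ids). With
#' two sites and one class each, site 1 holds every S0 patient and site 2
#' every S1plus patient — the extreme single-class-per-site scenario.
#'
#' @inheritParams dirichlet_class_partition
#' @param classes_per_site number of classes owned by each site (1 or 2 for
#'   the binary task).
#' @return list of site partitions.
#' @export
quantity_class_partition <- function(pool, n_sites, classes_per_site = 1L) {
  if (nrow(pool) == 0) stop("pool is empty")
  present <- CLASSES[CLASSES %in% pool$binary_class]
  if (classes_per_site * n_sites < length(present))
    stop("classes_per_site * n_sites must cover all classes present")
  owners <- setNames(vector("list", length(present)), present)
  slot <- 0L
  for (i in seq_len(n_sites)) {
    for (k in seq_len(classes_per_site)) {
      cl <- present[(slot %% length(present)) + 1L]
      owners[[cl]] <- unique(c(owners[[cl]], i))
      slot <- slot + 1L
    }
  }
  if (any(vapply(owners, length, integer(1)) == 0))
    stop("a class is owned by zero sites")
  assign <- setNames(vector("list", n_sites), seq_len(n_sites))
  for (cl in present) {
    ids <- pool$patient_id[pool$binary_class == cl]
    own <- sort(owners[[cl]])
    counts <- rep(length(ids) %/% length(own), length(own))
    extra <- length(ids) %% length(own)
    if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
    stops <- cumsum(counts)
    starts <- c(1L, head(stops, -1L) + 1L)
    for (j in seq_along(own))
      if (counts[j] > 0)
        assign[[own[j]]] <- c(assign[[own[j]]], ids[starts[j]:stops[j]])
  }
  sites <- lapply(seq_len(n_sites), function(i)
    new_site_partition(i, pool_rows(pool, assign[[i]])))
  assert_conservation(sites, pool)
}

#' Quantity skew: Dirichlet allocation of sample counts
#'
#' Site sizes are drawn from a symmetric Dirichlet with concentration
#' `beta` (largest-remainder rounding); patients are then dealt uniformly at
#' random without replacement, so each site's class composition approximates
#' the global distribution in expectation (no stratification).
#'
#' @inheritParams dirichlet_class_partition
#' @export
dirichlet_quantity_partition <- function(pool, n_sites, beta, seed = 1L) {
  if (nrow(pool) == 0) stop("pool is empty")
  if (beta <= 0) stop("beta must be > 0")
  with_seed(derive_seed(seed, 12L), {
    ids <- sample(pool$patient_id)
    counts <- apportion_lr(rdirichlet1(n_sites, beta), length(ids))
    stops <- cumsum(counts)
    starts <- c(1L, head(stops, -1L) + 1L)
    sites <- lapply(seq_len(n_sites), function(i) {
      sel <- if (counts[i] > 0) ids[starts[i]:stops[i]] else character(0)
      new_site_partition(i, pool_rows(pool, sel))
    })
    assert_conservation(sites, pool)
  })
}

#' Source-based partition: sites are the true centers of origin
#'
#' Site 1 receives every public-like patient and site 2 every private-like
#' patient, mirroring a real two-center federation. Empty sites are
#' permitted (and flagged downstream by the heterogeneity report).
#'
#' @param pool training-pool data.frame with a `site` column.
#' @export
source_partition <- function(pool) {
  sites <- list(
    new_site_partition(1L, pool[pool$site == "public_like", , drop = FALSE]),
    new_site_partition(2L, pool[pool$site == "private_like", , drop = FALSE]))
  assert_conservation(sites, pool)
}

#' Global-imbalance / local-heterogeneity scenario builder
#'
#' First subsamples a global set of `total_patients` with exactly a
#' largest-remainder share `s0_fraction` of class S0; then composes each
#' site's class distribution as the mixture
#' `P_i = alpha * P_global + (1 - alpha) * delta(c_i)`,
#' where `c_i` cycles through S0, S1plus by site index. `alpha = 1` makes
#' every site a copy of the global distribution; `alpha = 0` gives each site
#' a single class. Sites receive equal total shares; class counts are
#' reconciled so the global composition is conserved exactly.
#'
#' @inheritParams dirichlet_class_partition
#' @param total_patients size of the subsampled global set (default 84).
#' @param s0_fraction target global fraction of class S0, in (0, 1).
#' @param alpha local homogeneity level in \[0, 1\].
#' @export
imbalance_scenario <- function(pool, total_patients = 84L, s0_fraction = 0.5,
                               alpha = 1, n_sites = 2L, seed = 1L) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (s0_fraction <= 0 || s0_fraction >= 1)
    stop("s0_fraction must be in (0, 1)")
  global_counts <- apportion_lr(c(s0_fraction, 1 - s0_fraction),
                                total_patients)
  names(global_counts) <- CLASSES
  for (cl in CLASSES) {
    have <- sum(pool$binary_class == cl)
    if (have < global_counts[cl])
      stop("pool has ", have, " patients of class ", cl, "; need ",
           global_counts[cl])
  }
  with_seed(derive_seed(seed, 13L), {
    sampled <- lapply(CLASSES, function(cl)
      sample(pool$patient_id[pool$binary_class == cl], global_counts[cl]))
    names(sampled) <- CLASSES
    p_global <- global_counts / sum(global_counts)
    c_i <- CLASSES[((seq_len(n_sites) - 1L) %% length(CLASSES)) + 1L]
    # Site totals must reconcile the mixture with conservation: the summed
    # class demand sum_i n_i P_i(c) can equal the global composition for
    # every alpha only when the pinned (1 - alpha) mass of the sites
    # carrying class c adds up to the global share of c. Sizes therefore
    # interpolate between equal shares (alpha = 1) and class-proportional
    # shares (alpha = 0).
    owners <- table(factor(c_i, levels = CLASSES))
    size_w <- alpha / n_sites +
      (1 - alpha) * as.numeric(p_global[c_i] / owners[c_i])
    site_n <- apportion_lr(size_w, total_patients)
    target <- matrix(0L, n_sites, length(CLASSES),
                     dimnames = list(NULL, CLASSES))
    for (i in seq_len(n_sites)) {
      p_i <- alpha * p_global
      p_i[c_i[i]] <- p_i[c_i[i]] + (1 - alpha)
      target[i, ] <- apportion_lr(p_i, site_n[i])
    }
    # reconcile column totals with the global composition (binary classes:
    # one swap fixes both); move units at the site with the largest excess
    excess <- sum(target[, "S0"]) - global_counts["S0"]
    while (excess != 0) {
      if (excess > 0) {
        i <- which.max(target[, "S0"] - site_n * (alpha * p_global["S0"] +
               (1 - alpha) * (c_i == "S0")))
        target[i, "S0"] <- target[i, "S0"] - 1L
        target[i, "S1plus"] <- target[i, "S1plus"] + 1L
        excess <- excess - 1L
      } else {
        i <- which.max(target[, "S1plus"] - site_n * (alpha *
               p_global["S1plus"] + (1 - alpha) * (c_i == "S1plus")))
        target[i, "S1plus"] <- target[i, "S1plus"] - 1L
        target[i, "S0"] <- target[i, "S0"] + 1L
        excess <- excess + 1L
      }
    }
    if (alpha == 0 && any(target[cbind(seq_len(n_sites),
                                       match(c_i, CLASSES))] != site_n))
      stop("cannot pin single classes: insufficient patients of class ",
           paste(unique(c_i), collapse = "/"))
    ptr <- c(S0 = 0L, S1plus = 0L)
    sites <- lapply(seq_len(n_sites), function(i) {
      ids <- character(0)
      for (cl in CLASSES) {
        k <- target[i, cl]
        if (k > 0) {
          ids <- c(ids, sampled[[cl]][(ptr[cl] + 1L):(ptr[cl] + k)])
          ptr[cl] <<- ptr[cl] + k
        }
      }
      new_site_partition(i, pool_rows(pool, ids))
    })
    sub_pool <- pool[pool$patient_id %in% unlist(sampled), , drop = FALSE]
    assert_conservation(sites, sub_pool)
  })
}

#' Cosine similarity between a site's class counts and the global counts
#'
#' `CS_i = (v_i . V) / (||v_i|| ||V||)`, in (0, 1\] for non-negative
#' non-zero count vectors; 1 exactly when the site's class distribution is
#' proportional to the global one.
#'
#' @param v_i site class-count vector.
#' @param V global class-count vector.
#' @export
cosine_similarity_site <- function(v_i, V) {
  if (length(v_i) != length(V)) stop("v_i and V must have equal length")
  if (all(v_i == 0)) stop("v_i is a zero vector (empty site); filter it out")
  if (all(V == 0)) stop("V is a zero vector")
  sum(v_i * V) / (sqrt(sum(v_i^2)) * sqrt(sum(V^2)))
}

#' Size-weighted average cosine similarity of a partition
#'
#' `CS-bar = sum_i (n_i / n) CS_i` over non-empty sites, where `V` is the
#' summed class-count vector. 1 indicates every site matches the global
#' class distribution; lower values indicate local/global mismatch. Empty
#' sites are excluded from the metric (cosine similarity is undefined for a
#' zero vector) and flagged.
#'
#' @param sites list of site partitions.
#' @return list of class `"heterogeneity_report"`: `per_site_cs`,
#'   `weighted_cs`, `global_counts`, `n`, `empty_sites`.
#' @export
weighted_avg_cosine <- function(sites) {
  ns <- vapply(sites, function(s) s$n, numeric(1))
  if (all(ns == 0)) stop("all sites are empty")
  V <- Reduce(`+`, lapply(sites, function(s) s$class_counts))
  keep <- which(ns > 0)
  cs <- vapply(sites[keep], function(s)
    cosine_similarity_site(s$class_counts, V), numeric(1))
  per_site <- rep(NA_real_, length(sites))
  per_site[keep] <- cs
  n <- sum(ns)
  structure(list(per_site_cs = per_site,
                 weighted_cs = sum(ns[keep] / n * cs),
                 global_counts = V, n = n,
                 empty_sites = which(ns == 0)),
            class = "heterogeneity_report")
}

#' @export
print.heterogeneity_report <- function(x, ...) {
  cat("Partition heterogeneity: weighted average cosine similarity =",
      format(x$weighted_cs, digits = 4), "\n")
  cat("  global class counts:",
      paste(sprintf("%s=%d", names(x$global_counts), x$global_counts),
            collapse = ", "), " (n =", x$n, ")\n")
  cat("  per-site CS:", paste(format(x$per_site_cs, digits = 4),
                              collapse = ", "), "\n")
  if (length(x$empty_sites))
    cat("  empty sites (excluded):",
        paste(x$empty_sites, collapse = ", "), "\n")
  invisible(x)
}
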