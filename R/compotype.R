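# Composome detection and compotype clustering.
#
# A composome is a *self-reproducing* compositional assembly: a progeny whose
# composition is close (cosine similarity >= eta) to its parent's pre-split
# composition. Composomes are grouped into K "compotypes" by centroid-based
# clustering of their composition fractions; everything non-composomal forms
# the drift pool, so the per-generation compotype fractions P_k never sum
# above 1.

#' Compositional similarity of two assemblies
#'
#' The cosine of the angle between two composition vectors: 1 for identical
#' proportions, 0 for disjoint type usage. Scale-invariant, so assemblies of
#' different sizes compare by composition only.
#'
#' @param a,b Nonnegative, nonzero numeric vectors of equal length.
#' @return Scalar in \[0, 1\].
#' @examples
#' similarity(c(1, 1), c(1, 0))  # 1/sqrt(2)
#' @export
similarity <- function(a, b) {
  a <- as_counts(a); b <- as_counts(b)
  if (length(a) != length(b)) stop("vectors must have equal length",
                                   call. = FALSE)
  if (any(a < 0) || any(b < 0)) stop("vectors must be nonnegative",
                                     call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("similarity is undefined for a zero vector",
                               call. = FALSE)
  sum(a * b) / (na * nb)
}

#' Is a progeny a faithful reproduction of its parent?
#'
#' @param parent,progeny Assemblies or counts vectors.
#' @param eta Similarity threshold in (0, 1]; default 0.9.
#' @return `TRUE` iff `similarity(parent, progeny) >= eta`.
#' @export
is_composome <- function(parent, progeny, eta = 0.9) {
  similarity(parent, progeny) >= eta
}

# Rowwise cosine similarity of two matrices.
row_cosine <- function(a, b) {
  num <- rowSums(a * b)
  den <- sqrt(rowSums(a^2)) * sqrt(rowSums(b^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# Birth table of a trajectory: one row per assembly id with its composition,
# birth generation, parent id, and similarity to the parent's pre-split
# composition (reconstructed as progeny + sibling; NA for seed assemblies or
# when the sibling never entered the population).
trajectory_births <- function(trajectory) {
  rec <- trajectory$records
  ncols <- paste0("n_", seq_len(trajectory$n_types))
  births <- rec[!duplicated(rec$assembly_id), , drop = FALSE]
  counts <- as.matrix(births[, ncols])
  sim <- rep(NA_real_, nrow(births))
  has_parent <- !is.na(births$parent_id)
  if (any(has_parent)) {
    key <- paste(births$t[has_parent], births$parent_id[has_parent])
    grown <- rowsum(counts[has_parent, , drop = FALSE], key)
    n_sibs <- as.vector(table(key)[rownames(grown)])
    full <- grown[key, , drop = FALSE]
    ok <- n_sibs[match(key, rownames(grown))] == 2L
    s <- row_cosine(counts[has_parent, , drop = FALSE], full)
    s[!ok] <- NA_real_
    sim[has_parent] <- s
  }
  births$parent_similarity <- sim
  births
}

#' Cluster a trajectory's composomes into compotypes
#'
#' Marks composomal assemblies (parent-progeny similarity >= `eta`),
#' partitions their composition fractions into `k` clusters by k-means with
#' deterministic seeded restarts, and returns the per-generation population
#' fractions P_k(t), centroid profiles, mean sizes and drift fraction.
#'
#' Assemblies that are not composomes are never assigned to a compotype; they
#' form the drift pool, so at every generation `sum(P_k) + drift == 1`.
#'
#' @param trajectory A `gard_trajectory` from [run_reactor()] or
#'   [read_trajectory()].
#' @param k Number of compotypes (default 3).
#' @param eta Composome similarity threshold (default 0.9).
#' @param seed Seed for the clustering restarts (clustering is deterministic
#'   given the seed; labels are canonically ordered by decreasing abundance).
#' @param weighting `"assemblies"` (P_k = fraction of assemblies, default) or
#'   `"molecules"` (P_k = fraction of molecules).
#' @return A `gard_compotype_series`: list with `t`, `P` (generations x k
#'   matrix), `drift`, `profiles` (k x N_G, rows sum to 1), `N_k` (mean
#'   assembly size per compotype), `assignments`, `eta`, `k`, `env`,
#'   `env_schedule`.
#' @export
cluster_compotypes <- function(trajectory, k = 3, eta = 0.9, seed = 1L,
                               weighting = c("assemblies", "molecules")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(trajectory, "gard_trajectory"))
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  nG <- trajectory$n_types
  ncols <- paste0("n_", seq_len(nG))
  births <- trajectory_births(trajectory)
  comp <- !is.na(births$parent_similarity) & births$parent_similarity >= eta
  n_comp <- sum(comp)
  if (n_comp < k) {
    stop("only ", n_comp, " composomal assemblies found but k = ", k,
         "; lower k or eta", call. = FALSE)
  }
  counts <- as.matrix(births[comp, ncols, drop = FALSE])
  fracs <- counts / rowSums(counts)
  n_distinct <- nrow(unique(round(fracs, 12)))
  if (n_distinct < k) {
    stop("only ", n_distinct, " distinct composomal compositions but k = ",
         k, "; lower k or eta", call. = FALSE)
  }
  km <- with_local_seed(seed,
                        stats::kmeans(fracs, centers = k, nstart = 10,
                                      iter.max = 100))
  label_of <- stats::setNames(km$cluster, births$assembly_id[comp])

  rec <- trajectory$records
  rec_label <- label_of[as.character(rec$assembly_id)]
  rec_label[is.na(rec_label)] <- 0L
  w <- if (weighting == "molecules") rowSums(rec[, ncols]) else
    rep(1, nrow(rec))

  n_gen <- max(rec$t)
  P <- matrix(0, n_gen, k)
  tot <- rowsum(w, rec$t)
  for (kk in seq_len(k)) {
    sel <- rec_label == kk
    if (any(sel)) {
      part <- rowsum(w[sel], rec$t[sel])
      P[as.integer(rownames(part)), kk] <- part / tot[rownames(part), 1]
    }
  }
  drift <- 1 - rowSums(P)

  # Canonical label order: most abundant compotype first (time-summed P),
  # ties broken by the centroid profile.
  profiles <- km$centers / rowSums(km$centers)
  ord <- order(-colSums(P), apply(profiles, 1, paste, collapse = ","))
  P <- P[, ord, drop = FALSE]
  profiles <- profiles[ord, , drop = FALSE]
  relabel <- match(seq_len(k), ord)

  sizes <- rowSums(rec[, ncols])
  N_k <- vapply(seq_len(k), function(kk) {
    sel <- rec_label == ord[kk]
    if (any(sel)) stats::weighted.mean(sizes[sel], w[sel]) else NA_real_
  }, numeric(1))

  assignments <- data.frame(
    assembly_id = births$assembly_id,
    t_birth = births$t,
    parent_id = births$parent_id,
    parent_similarity = births$parent_similarity,
    compotype = ifelse(comp, relabel[unname(label_of[
      as.character(births$assembly_id)])], NA_integer_)
  )
  colnames(P) <- paste0("P_", seq_len(k))
  rownames(profiles) <- paste0("compotype_", seq_len(k))

  structure(
    list(t = seq_len(n_gen), P = P, drift = drift, profiles = profiles,
         N_k = N_k, assignments = assignments, eta = eta, k = k,
         weighting = weighting, env = trajectory$env,
         env_schedule = trajectory$env_schedule),
    class = "gard_compotype_series"
  )
}

#' @export
print.gard_compotype_series <- function(x, ...) {
  cat("<gard_compotype_series> ", length(x$t), " generations, ", x$k,
      " compotypes (eta = ", x$eta, ")\n", sep = "")
  cat("  final P_k: ", paste(signif(x$P[nrow(x$P), ], 3), collapse = " "),
      "; final drift: ", signif(x$drift[length(x$drift)], 3), "\n", sep = "")
  invisible(x)
}

# Running mean with shrinking windows at the edges.
runmean <- function(x, w) {
  n <- length(x)
  if (w <= 1 || n < 3) return(x)
  half <- floor(w / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Detect takeover episodes between compotypes
#'
#' A takeover is an interval over which one compotype's (smoothed) population
#' fraction falls while another's rises, the two crossing in between -- the
#' signature by which one composome population displaces another.
#'
#' @param series A `gard_compotype_series`.
#' @param window Smoothing window (generations) for the running mean.
#' @param min_change Minimum rise of the winner and fall of the loser
#'   (in absolute fraction) for an episode to be reported.
#' @return Data frame with columns `k_declining`, `k_rising`, `start`, `end`,
#'   `crossing`; zero rows when no takeover occurred.
#' @export
takeover_summary <- function(series, window = 101, min_change = 0.05) {
  stopifnot(inherits(series, "gard_compotype_series"))
  P <- series$P
  if (nrow(P) < 2) stop("series must span at least 2 generations",
                        call. = FALSE)
  k <- ncol(P)
  sm <- apply(P, 2, runmean, w = window)
  out <- list()
  tol <- 1e-9
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a == b) next
    d <- sm[, a] - sm[, b]   # a leading while positive
    i <- 1L
    n <- length(d)
    while (i < n) {
      above <- which(d[i:n] > tol)
      if (!length(above)) break
      up <- i + above[1] - 1L
      below <- which(d[up:n] < -tol)
      if (!length(below)) break
      down <- up + below[1] - 1L
      crossing <- down - 1L
      start <- up - 1L + which.max(d[up:down])
      rest <- which.min(d[down:n])
      end <- down - 1L + rest
      fall <- sm[start, a] - sm[end, a]
      rise <- sm[end, b] - sm[start, b]
      if (fall >= min_change && rise >= min_change) {
        out[[length(out) + 1L]] <- data.frame(
          k_declining = a, k_rising = b, start = start, end = end,
          crossing = crossing)
      }
      i <- end + 1L
    }
  }
  if (!length(out)) {
    return(data.frame(k_declining = integer(), k_rising = integer(),
                      start = integer(), end = integer(),
                      crossing = integer()))
  }
  do.call(rbind, out)
}
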