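# Repertoire diversity and overlap statistics.

#' D50 diversity index
#'
#' The smallest number k of clones, taken in descending count order (ties
#' broken by clone key for determinism), whose cumulative count reaches at
#' least half the TCR pool; the index expresses k as a percentage of the
#' number of distinct clones. Lower values indicate oligoclonality.
#'
#' @param rep A non-empty \code{repertoire}.
#' @return List with \code{k} (integer) and \code{index} (percent in
#'   (0, 100]).
#' @export
d50 <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  if (rep$pool_size < 1L) stop("empty repertoire", call. = FALSE)
  cl <- rep$clones
  ord <- order(-cl$count, cl$clone_id, method = "radix")
  cum <- cumsum(cl$count[ord])
  k <- which(cum >= 0.5 * rep$pool_size)[1]
  list(k = as.integer(k), index = 100 * k / nrow(cl))
}

#' Analytic rarefaction curve
#'
#' Expected distinct-clone richness under subsampling without replacement:
#' E[S_m] = sum_i (1 - C(N - n_i, m) / C(N, m)), the hypergeometric
#' expectation, evaluated in log space for numerical safety. At m = N the
#' curve equals the observed richness exactly.
#'
#' @param rep A non-empty \code{repertoire}.
#' @param depths Integer subsampling depths in [1, pool_size]; defaults to
#'   ~20 evenly spaced depths up to the pool size.
#' @return Data frame (class \code{rarefaction_curve}) with columns
#'   \code{depth} and \code{expected_richness}.
#' @export
rarefaction <- function(rep, depths = NULL) {
  stopifnot(inherits(rep, "repertoire"))
  N <- rep$pool_size
  if (N < 1L) stop("empty repertoire", call. = FALSE)
  if (is.null(depths)) {
    depths <- unique(round(seq(1, N, length.out = min(20L, N))))
  }
  depths <- as.integer(depths)
  if (any(depths < 1L) || any(depths > N)) {
    stop("depths must lie in [1, pool_size = ", N, "]", call. = FALSE)
  }
  n_i <- rep$clones$count
  expected <- vapply(depths, function(m) {
    # log C(N - n_i, m) - log C(N, m); clones with n_i > N - m always appear
    keep <- (N - n_i) >= m
    p_absent <- numeric(length(n_i))
    p_absent[keep] <- exp(lchoose(N - n_i[keep], m) - lchoose(N, m))
    sum(1 - p_absent)
  }, numeric(1))
  out <- data.frame(depth = depths, expected_richness = expected)
  class(out) <- c("rarefaction_curve", "data.frame")
  out
}

#' Monte-Carlo rarefaction (cross-check mode)
#'
#' Resampling estimate of the rarefaction expectation; used only to verify
#' the analytic curve.
#'
#' @param rep A \code{repertoire}.
#' @param depths Subsampling depths.
#' @param n_draws Number of subsamples per depth.
#' @param seed RNG seed.
#' @return Data frame depth, mean_richness, se.
#' @export
rarefaction_mc <- function(rep, depths, n_draws = 1000L, seed = 1L) {
  stopifnot(inherits(rep, "repertoire"))
  N <- rep$pool_size
  pool <- rep(seq_len(nrow(rep$clones)), rep$clones$count)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  res <- lapply(as.integer(depths), function(m) {
    rich <- vapply(seq_len(n_draws), function(i) {
      length(unique(sample(pool, m, replace = FALSE)))
    }, numeric(1))
    c(mean = mean(rich), se = stats::sd(rich) / sqrt(n_draws))
  })
  data.frame(depth = as.integer(depths),
             mean_richness = vapply(res, `[[`, numeric(1), "mean"),
             se = vapply(res, `[[`, numeric(1), "se"))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Jaccard index of two repertoires
#'
#' Presence/absence overlap of clonotype identity sets:
#' |A intersect B| / |A union B|. Two empty repertoires give 0 with a
#' warning.
#'
#' @param rep_a,rep_b \code{repertoire} objects.
#' @return Real in [0, 1].
#' @export
jaccard_index <- function(rep_a, rep_b) {
  stopifnot(inherits(rep_a, "repertoire"), inherits(rep_b, "repertoire"))
  a <- rep_a$clones$clone_id
  b <- rep_b$clones$clone_id
  u <- length(union(a, b))
  if (u == 0L) {
    warning("both repertoires empty; Jaccard defined as 0", call. = FALSE)
    return(0)
  }
  length(intersect(a, b)) / u
}

#' Pairwise Jaccard matrix over repertoires
#' @param repertoires Named list of \code{repertoire} objects.
#' @return Symmetric matrix with unit diagonal (for non-empty repertoires).
#' @export
jaccard_matrix <- function(repertoires) {
  n <- length(repertoires)
  ids <- vapply(repertoires, `[[`, character(1), "sample_id")
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      v <- jaccard_index(repertoires[[i]], repertoires[[j]])
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  m
}
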