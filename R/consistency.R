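## Registration-consistency framework: pairwise inter-subject Pearson
## correlations of surface CBF maps, per-participant mean CC, and the
## method / group comparisons built on them.

#' Pairwise vertex-wise Pearson correlations within a group
#'
#' Enumerates every unordered pair of participants once and correlates their
#' surface CBF values over the vertices valid in both maps. Pairs with fewer
#' than 3 common valid vertices are undefined and logged.
#'
#' @param surface_maps list of `surface_map`s for one group and one
#'   registration method (ids taken from the maps, else positional).
#' @param group,method labels stored on the result.
#' @return list of class `pairwise_cc_set`: `pairs` (data.frame id_a, id_b,
#'   cc), `group`, `method`, `n_pairs`, `log`.
#' @export
pairwise_cc <- function(surface_maps, group = NA_character_,
                        method = NA_character_) {
  n <- length(surface_maps)
  if (n < 2) stop("need at least 2 maps")
  len <- vapply(surface_maps, function(m) length(m$values), integer(1))
  if (length(unique(len)) != 1) stop("maps have different vertex counts")
  ids <- vapply(seq_len(n), function(i) {
    id <- surface_maps[[i]]$id
    if (is.null(id)) sprintf("p%03d", i) else id
  }, character(1))
  rows <- vector("list", n * (n - 1) / 2)
  log <- character(0)
  k <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      k <- k + 1L
      ok <- surface_maps[[i]]$valid & surface_maps[[j]]$valid
      cc <- if (sum(ok) < 3) {
        log <- c(log, sprintf("pair (%s, %s) undefined: %d common valid vertices",
                              ids[i], ids[j], sum(ok)))
        NA_real_
      } else {
        stats::cor(surface_maps[[i]]$values[ok], surface_maps[[j]]$values[ok])
      }
      rows[[k]] <- data.frame(id_a = ids[i], id_b = ids[j], cc = cc,
                              stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  structure(list(pairs = pairs, group = group, method = method,
                 n_pairs = nrow(pairs), log = log),
            class = "pairwise_cc_set")
}

#' @export
print.pairwise_cc_set <- function(x, ...) {
  cat(sprintf("pairwise_cc_set [%s / %s]: %d pairs, mean CC %.4f\n",
              x$group, x$method, x$n_pairs, mean(x$pairs$cc, na.rm = TRUE)))
  invisible(x)
}

#' Combine the CC sets of the two patient groups
#'
#' Concatenates pair lists without forming any cross-group pair, so e.g.
#' 210 + 91 within-group pairs combine to 301.
#' @param cc_a,cc_b `pairwise_cc_set`s for the same registration method.
#' @export
combine_patient_groups <- function(cc_a, cc_b) {
  if (!identical(cc_a$method, cc_b$method))
    stop("cannot combine CC sets from different registration methods")
  structure(list(pairs = rbind(cc_a$pairs, cc_b$pairs),
                 group = paste(cc_a$group, cc_b$group, sep = "+"),
                 method = cc_a$method,
                 n_pairs = cc_a$n_pairs + cc_b$n_pairs,
                 log = c(cc_a$log, cc_b$log)),
            class = "pairwise_cc_set")
}

#' Mean participant CC
#'
#' Each participant's consistency score: the arithmetic mean of the CC
#' values of every pair the participant belongs to (n - 1 values in a group
#' of n).
#' @param ccset a `pairwise_cc_set`.
#' @return data.frame: `id`, `mean_cc`, `n_pairs`.
#' @export
mean_participant_cc <- function(ccset) {
  p <- ccset$pairs
  ids <- sort(unique(c(p$id_a, p$id_b)))
  out <- do.call(rbind, lapply(ids, function(id) {
    sel <- p$id_a == id | p$id_b == id
    data.frame(id = id, mean_cc = mean(p$cc[sel], na.rm = TRUE),
               n_pairs = sum(sel), stringsAsFactors = FALSE)
  }))
  out$method <- ccset$method
  out$group <- ccset$group
  out
}

# Pooled two-sample t-test that tolerates zero-variance inputs (tiny
# groups): no variance and equal means gives t = 0, p = 1.
pooled_t2 <- function(a, b) {
  df0 <- length(a) + length(b) - 2
  v <- c(stats::var(a), stats::var(b))
  if (anyNA(v) || sum(v) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(statistic = 0, parameter = df0, p.value = 1))
    return(list(statistic = sign(mean(a) - mean(b)) * Inf, parameter = df0,
                p.value = 0))
  }
  stats::t.test(a, b, var.equal = TRUE)
}

# Two-sample Cohen's d with pooled SD; undefined below 3 observations.
cohens_d_pooled <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na + nb < 3) return(NA_real_)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2))
  if (!is.finite(sp)) return(NA_real_)
  if (sp == 0) return(0)
  (mean(a) - mean(b)) / sp
}

#' Compare two registration methods' CC distributions
#'
#' Paired mode (default) runs a t-test on per-pair CC differences
#' (`df = n_pairs - 1`); `two_sample_pooled` runs an equal-variance
#' two-sample t-test on the two CC samples (`df = 2 n_pairs - 2`). Cohen's d
#' is always the pooled two-sample standardised mean difference of the CC
#' distributions. Undefined pairs are dropped listwise in paired mode.
#'
#' @param cc_a,cc_b `pairwise_cc_set`s over the same group.
#' @param test_kind `"paired"` or `"two_sample_pooled"`.
#' @return list of class `method_comparison`: `method_a`, `method_b`,
#'   `t_statistic`, `df`, `p_value`, `cohens_d`, `test_kind`,
#'   `mean_a`, `mean_b`.
#' @export
compare_methods <- function(cc_a, cc_b,
                            test_kind = c("paired", "two_sample_pooled")) {
  test_kind <- match.arg(test_kind)
  pa <- cc_a$pairs
  pb <- cc_b$pairs
  if (test_kind == "paired") {
    key_a <- paste(pa$id_a, pa$id_b)
    key_b <- paste(pb$id_a, pb$id_b)
    if (!setequal(key_a, key_b)) stop("paired comparison needs identical pair sets")
    pb <- pb[match(key_a, key_b), ]
    ok <- !is.na(pa$cc) & !is.na(pb$cc)
    d <- pa$cc[ok] - pb$cc[ok]
    if (length(d) < 2) {
      tt <- list(statistic = NA_real_, parameter = max(0, length(d) - 1),
                 p.value = NA_real_)
    } else if (stats::sd(d) == 0) {
      tt <- list(statistic = 0, parameter = length(d) - 1, p.value = 1)
    } else {
      tt <- stats::t.test(pa$cc[ok], pb$cc[ok], paired = TRUE)
    }
    a_vals <- pa$cc[ok]; b_vals <- pb$cc[ok]
  } else {
    a_vals <- pa$cc[!is.na(pa$cc)]
    b_vals <- pb$cc[!is.na(pb$cc)]
    tt <- pooled_t2(a_vals, b_vals)
  }
  structure(list(method_a = cc_a$method, method_b = cc_b$method,
                 t_statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value,
                 cohens_d = cohens_d_pooled(a_vals, b_vals),
                 test_kind = test_kind,
                 mean_a = mean(a_vals), mean_b = mean(b_vals)),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s (%s): t(%g) = %.3f, p = %.3g, d = %.3f\n",
              x$method_a, x$method_b, x$test_kind, x$df, x$t_statistic,
              x$p_value, x$cohens_d))
  invisible(x)
}

#' Compare mean participant CC between two groups
#'
#' Pooled-variance two-sample t-test on the per-participant mean CC values;
#' `df = n_a + n_b - 2` (so 50 controls vs 14 patients gives t(62)).
#' @param participants_a,participants_b data.frames from
#'   [mean_participant_cc()] (or numeric vectors of mean CC).
#' @return `method_comparison` with `test_kind = "two_sample_pooled"`.
#' @export
compare_groups_mean_cc <- function(participants_a, participants_b) {
  a <- if (is.data.frame(participants_a)) participants_a$mean_cc else participants_a
  b <- if (is.data.frame(participants_b)) participants_b$mean_cc else participants_b
  stopifnot(length(a) >= 2, length(b) >= 2)
  tt <- pooled_t2(a, b)
  structure(list(method_a = "group_a", method_b = "group_b",
                 t_statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value,
                 cohens_d = cohens_d_pooled(a, b),
                 test_kind = "two_sample_pooled",
                 mean_a = mean(a), mean_b = mean(b)),
            class = "method_comparison")
}
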