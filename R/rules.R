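#' Candidate split thresholds for one dose feature
#'
#' Midpoints between consecutive distinct sorted values, thinned to at most
#' `max_candidates` thresholds at evenly spaced quantiles of the midpoint
#' list.  Deterministic; a constant column yields no candidates.
#'
#' @param values numeric feature column.
#' @param max_candidates cap on the number of thresholds.
#' @return numeric vector of thresholds (possibly empty).
#' @export
candidate_thresholds <- function(values, max_candidates = 64) {
  u <- sort(unique(values[is.finite(values)]))
  if (length(u) < 2L) return(numeric(0))
  mids <- (u[-1] + u[-length(u)]) / 2
  if (length(mids) > max_candidates)
    mids <- unname(stats::quantile(mids,
                                   probs = seq(0, 1,
                                               length.out = max_candidates),
                                   type = 7))
  unique(mids)
}

#' Empirical mutual information of two binary vectors (bits)
#'
#' Plug-in estimate from the 2x2 contingency table, base 2, with the
#' convention 0 * log 0 = 0.
#'
#' @param split,target logical (or 0/1) vectors of equal length.
#' @return mutual information in bits, >= 0.
#' @export
mutual_information <- function(split, target) {
  split <- as.logical(split); target <- as.logical(target)
  if (length(split) != length(target))
    stop("split and target lengths differ", call. = FALSE)
  n <- length(split)
  a <- sum(split & target)
  b <- sum(split & !target)
  c <- sum(!split & target)
  d <- n - a - b - c
  mi_counts(a, b, c, d, n)
}

# vectorized plug-in MI from 2x2 counts (a = s&y, b = s&!y, c = !s&y, d rest)
mi_counts <- function(a, b, c, d, n) {
  term <- function(nij, ni, nj) {
    out <- numeric(length(nij))
    pos <- nij > 0
    out[pos] <- (nij[pos] / n) *
      log2(n * nij[pos] / (ni[pos] * nj[pos]))
    out
  }
  s1 <- a + b; s0 <- c + d; y1 <- a + c; y0 <- b + d
  term(a, s1, y1) + term(b, s1, y0) + term(c, s0, y1) + term(d, s0, y0)
}

# build the pool of candidate splits for a feature matrix:
# S (n x m logical), plus feature names and thresholds per column
split_pool <- function(features, max_candidates = 64) {
  fn <- colnames(features)
  cols <- list(); feat <- character(); thr <- numeric()
  for (j in seq_along(fn)) {
    th <- candidate_thresholds(features[, j], max_candidates)
    if (!length(th)) next
    cols[[length(cols) + 1L]] <- outer(features[, j], th, ">")
    feat <- c(feat, rep(fn[j], length(th)))
    thr <- c(thr, th)
  }
  if (!length(cols))
    return(list(S = matrix(FALSE, nrow(features), 0), feature = character(),
                threshold = numeric()))
  list(S = do.call(cbind, cols) * 1, feature = feat, threshold = thr)
}

#' Distill high-dose membership into threshold rules by beam search
#'
#' Finds a small conjunction of exceedance rules (`feature > threshold`,
#' ANDed) whose satisfied group — the simplified high-dose (SHD) group —
#' maximizes mutual information with high-dose cluster membership.  Depth 1
#' scores every (feature, threshold) split and keeps the top `beam_width`
#' by MI; at each further depth every beam conjunction is extended by every
#' split and the global top `beam_width` conjunctions (scored as the full
#' conjunction against the full cohort) are kept.  Search stops at
#' `max_depth` or when no extension strictly increases MI.  The single best
#' conjunction is returned; ties prefer higher recall, then fewer rules,
#' then lexicographic feature names, then lower thresholds.
#'
#' @param features numeric matrix (patients x features) with column names.
#' @param hd_labels logical vector of high-dose membership, same length as
#'   `nrow(features)`.
#' @param beam_width beam size (25 matches the reference procedure).
#' @param max_depth maximum number of rules in the conjunction.
#' @param max_candidates per-feature threshold cap, see
#'   [candidate_thresholds()].
#' @return an object of class `"rule_set"`: a list with `rules` (data.frame
#'   feature/threshold/direction), `mi_bits`, `precision`, `recall`,
#'   `n_shd`, `n_hd`.
#' @export
beam_search_rules <- function(features, hd_labels, beam_width = 25,
                              max_depth = 2, max_candidates = 64) {
  features <- as.matrix(features)
  y <- as.logical(hd_labels)
  stopifnot(length(y) == nrow(features))
  if (!any(y) || all(y))
    stop("hd_labels needs at least one positive and one negative",
         call. = FALSE)
  pool <- split_pool(features, max_candidates)
  if (ncol(pool$S) == 0L) {
    warning("all features constant; empty rule set returned")
    return(empty_rule_set(y))
  }
  n <- nrow(features)
  npos <- sum(y)
  m <- ncol(pool$S)
  score_members <- function(member) {
    # member: logical n-vector (current conjunction); MI of every extension
    # `member AND split_j` against the full-cohort labels
    tp <- as.numeric(crossprod(pool$S, member & y))
    sz <- as.numeric(crossprod(pool$S, member))
    mi_counts(tp, sz - tp, npos - tp, n - sz - npos + tp, n)
  }
  mk_entry <- function(idx) {
    member <- rowSums(pool$S[, idx, drop = FALSE]) == length(idx)
    list(idx = idx, member = member,
         mi = mutual_information(member, y),
         recall = sum(member & y) / npos)
  }
  # keep the top `width` by MI, tie-inclusive at the cutoff (bounded)
  top_tied <- function(mi, width) {
    ord <- order(-mi)
    if (length(ord) <= width) return(ord)
    cutoff <- mi[ord[width]]
    utils::head(ord[mi[ord] >= cutoff - 1e-12], max(4L * width, 200L))
  }
  rank_entries <- function(entries) {
    keys <- list(
      -vapply(entries, `[[`, numeric(1), "mi"),
      -vapply(entries, `[[`, numeric(1), "recall"),
      vapply(entries, function(e) length(e$idx), numeric(1)),
      vapply(entries, function(e)
        paste(sort(pool$feature[e$idx]), collapse = "|"), character(1)),
      vapply(entries, function(e)
        paste(sprintf("%020.9f", sort(pool$threshold[e$idx])),
              collapse = "|"), character(1)))
    order_by_keys(keys)
  }
  # depth 1: every split scored against the full cohort
  mi1 <- score_members(rep(TRUE, n))
  beam <- lapply(top_tied(mi1, beam_width), mk_entry)
  best <- beam[[rank_entries(beam)[1L]]]
  depth <- 1L
  while (depth < max_depth) {
    parent_idx <- list(); parent_mi <- list()
    for (b in seq_along(beam)) {
      mis <- score_members(beam[[b]]$member)
      mis[beam[[b]]$idx] <- -Inf            # no repeated split
      keep <- top_tied(mis, beam_width)
      parent_idx[[b]] <- keep
      parent_mi[[b]] <- mis[keep]
    }
    cand_parent <- rep(seq_along(beam),
                       vapply(parent_idx, length, integer(1)))
    cand_ext <- unlist(parent_idx)
    cand_mi <- unlist(parent_mi)
    if (!length(cand_mi)) break
    sel <- top_tied(cand_mi, beam_width)
    # dedupe conjunctions that are the same split set via canonical keys
    keys <- vapply(sel, function(i)
      paste(sort(c(beam[[cand_parent[i]]]$idx, cand_ext[i])),
            collapse = "+"), character(1))
    sel <- sel[!duplicated(keys)]
    new_beam <- lapply(sel, function(i)
      mk_entry(c(beam[[cand_parent[i]]]$idx, cand_ext[i])))
    cand_best <- new_beam[[rank_entries(new_beam)[1L]]]
    if (cand_best$mi <= best$mi + 1e-12) break   # no strict MI gain
    beam <- new_beam
    best <- cand_best
    depth <- depth + 1L
  }
  rules <- data.frame(feature = pool$feature[best$idx],
                      threshold = pool$threshold[best$idx],
                      direction = ">", stringsAsFactors = FALSE)
  rules <- rules[order(rules$feature, rules$threshold), , drop = FALSE]
  rownames(rules) <- NULL
  finalize_rule_set(rules, features, y)
}

empty_rule_set <- function(y) {
  structure(list(rules = data.frame(feature = character(),
                                    threshold = numeric(),
                                    direction = character()),
                 mi_bits = 0, precision = 0, recall = 0,
                 n_shd = 0L, n_hd = sum(y)),
            class = "rule_set")
}

finalize_rule_set <- function(rules, features, y) {
  member <- shd_membership_df(rules, features)
  tp <- sum(member & y)
  prec <- if (any(member)) tp / sum(member) else 0
  structure(list(rules = rules,
                 mi_bits = mutual_information(member, y),
                 precision = prec, recall = tp / sum(y),
                 n_shd = sum(member), n_hd = sum(y)),
            class = "rule_set")
}

shd_membership_df <- function(rules, features) {
  if (!nrow(rules)) return(rep(FALSE, nrow(features)))
  member <- rep(TRUE, nrow(features))
  for (i in seq_len(nrow(rules)))
    member <- member & features[, rules$feature[i]] > rules$threshold[i]
  member
}

#' Simplified high-dose membership under a rule set
#'
#' A patient belongs to the SHD group when it exceeds every threshold in the
#' conjunction.
#'
#' @param rs a [beam_search_rules()] result.
#' @param features feature matrix containing the rule features.
#' @return logical vector, one entry per row of `features`.
#' @export
shd_membership <- function(rs, features) {
  stopifnot(inherits(rs, "rule_set"))
  shd_membership_df(rs$rules, as.matrix(features))
}

#' Precision, recall and MI of a rule set against HD labels
#'
#' @param rs a [beam_search_rules()] result.
#' @param features feature matrix.
#' @param hd_labels logical high-dose membership.
#' @return a list with `precision`, `recall`, `mi_bits`, `undefined`
#'   (TRUE when the SHD group is empty and precision is reported as 0).
#' @export
rule_quality <- function(rs, features, hd_labels) {
  y <- as.logical(hd_labels)
  member <- shd_membership(rs, features)
  tp <- sum(member & y)
  undef <- !any(member)
  list(precision = if (undef) 0 else tp / sum(member),
       recall = if (any(y)) tp / sum(y) else 0,
       mi_bits = mutual_information(member, y),
       undefined = undef)
}

#' @export
print.rule_set <- function(x, ...) {
  cat("<rule_set> simplified high-dose group\n")
  if (!nrow(x$rules)) {
    cat("  (empty)\n")
  } else {
    for (i in seq_len(nrow(x$rules)))
      cat(sprintf("  %s %s %.4g Gy  [display: > %d]\n", x$rules$feature[i],
                  x$rules$direction[i], x$rules$threshold[i],
                  round(x$rules$threshold[i])))
  }
  cat(sprintf("  precision %.3f, recall %.3f, MI %.3f bits (n_SHD=%d, n_HD=%d)\n",
              x$precision, x$recall, x$mi_bits, x$n_shd, x$n_hd))
  invisible(x)
}
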