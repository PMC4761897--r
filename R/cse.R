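## Context-specific expression (CSE) and per-TF trans-activity testing.
## CSE contrasts the same parental allele across hybrid partner contexts:
## CSE(a, b) = 2 * Expr(a, b) / (Expr(a, c) + Expr(a, d)), where Expr(a, b)
## is the TMM-normalized, replicate-averaged expression of the a allele in
## the a x b hybrid. A CSE above 1 means the partner (foreground) strain b
## trans-activates the allele more than the background strains do.

#' Replicate-mean normalized allele expression per hybrid context
#'
#' TMM-normalizes the full count table (all hybrids jointly, so values are
#' comparable across crosses), converts counts to a common library scale and
#' averages replicates, yielding one expression value per (gene, allele,
#' partner strain) combination.
#'
#' @param x an [allele_counts()] covering all hybrids.
#' @return A numeric matrix genes x contexts with columns named
#'   `"<allele>_in_<partner>"`.
#' @export
allele_expression <- function(x) {
  stopifnot(inherits(x, "allele_counts"))
  if (anyNA(x$samples$norm.factors)) x <- tmm_factors(x)
  eff <- effective_libsize(x)
  norm <- sweep(x$counts, 2L, mean(eff) / eff, `*`)
  partner <- vapply(seq_len(ncol(norm)), function(j) {
    parts <- strsplit(x$samples$hybrid[j], "x", fixed = TRUE)[[1L]]
    setdiff(parts, x$samples$allele[j])
  }, character(1))
  ctx <- paste0(x$samples$allele, "_in_", partner)
  ctxs <- unique(ctx)
  out <- vapply(ctxs, function(cc)
    rowMeans(norm[, ctx == cc, drop = FALSE]), numeric(nrow(norm)))
  rownames(out) <- rownames(x$counts)
  out
}

#' Context-specific expression of one allele in one foreground context
#'
#' `CSE = 2 * (Expr(a, b) + eps) / ((Expr(a, c) + eps) + (Expr(a, d) + eps))`
#' for query allele `a`, foreground strain `b` and the two background
#' strains `c, d`. The pseudocount `eps` guards division by zero; genes
#' whose background expression is zero in both contexts before
#' pseudocounting are flagged invalid.
#'
#' @param expr matrix from [allele_expression()].
#' @param query query allele strain `a`.
#' @param foreground foreground strain `b` (the hybrid partner whose
#'   trans-activity is probed); must differ from `query`.
#' @param backgrounds the two background strains (default: all remaining
#'   strains in `expr`).
#' @param eps pseudocount on normalized expression (default 0.5).
#' @return data.frame of class `cse_table`: gene, query, foreground, cse,
#'   log2_cse, valid.
#' @export
compute_cse <- function(expr, query, foreground, backgrounds = NULL,
                        eps = 0.5) {
  ctx <- function(a, b) paste0(a, "_in_", b)
  strains <- unique(sub("_in_.*", "", colnames(expr)))
  if (query == foreground) stopf("query must differ from the foreground strain")
  backgrounds <- backgrounds %||% setdiff(strains, c(query, foreground))
  if (length(backgrounds) != 2L) stopf("need exactly two background strains")
  if (query %in% backgrounds)
    stopf("query must differ from the background strains")
  need <- ctx(query, c(foreground, backgrounds))
  if (!all(need %in% colnames(expr)))
    stopf("missing hybrid context(s): %s",
          paste(setdiff(need, colnames(expr)), collapse = ", "))
  fg <- expr[, need[1L]]
  b1 <- expr[, need[2L]]
  b2 <- expr[, need[3L]]
  cse <- 2 * (fg + eps) / ((b1 + eps) + (b2 + eps))
  valid <- !(b1 == 0 & b2 == 0)
  structure(data.frame(gene = rownames(expr), query = query,
                       foreground = foreground, cse = cse,
                       log2_cse = log2(cse), valid = valid,
                       row.names = NULL),
            class = c("cse_table", "data.frame"))
}

#' Define a TF's target genes from motif scores
#'
#' Targets are the genes scoring at least half the maximum observed motif
#' score; if fewer than `min_n` genes qualify the top `min_n` are taken, and
#' if more than `max_frac` of the scored genes qualify only the top
#' `floor(max_frac * n)` are kept. Ties at a cutoff are broken by
#' lexicographic gene id.
#'
#' @param scores named non-negative numeric vector, one score per gene with
#'   a scannable promoter (e.g. [motif_score_max()] values).
#' @param min_n minimum target-set size (default 50).
#' @param max_frac maximum fraction of scored genes (default 0.10).
#' @return Character vector of target gene ids.
#' @export
define_targets <- function(scores, min_n = 50, max_frac = 0.10) {
  if (length(scores) == 0L) stopf("empty score vector")
  if (is.null(names(scores))) stopf("scores must be named by gene")
  total <- length(scores)
  ord <- order(-scores, names(scores))
  s <- names(scores)[scores >= max(scores) / 2]
  cap <- floor(max_frac * total)
  if (length(s) < min_n) {
    s <- names(scores)[ord][seq_len(min(min_n, total))]
  } else if (length(s) > cap) {
    s <- names(scores)[ord][seq_len(max(cap, 1L))]
  }
  s
}

## Welch two-sample t on log2 CSE, targets vs non-targets. Hand-rolled so
## degenerate inputs (identical constant groups) return t = 0, p = 1 instead
## of erroring.
.welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L)
    return(list(t = NA_real_, p = NA_real_, mean_diff = NA_real_,
                df = NA_real_, testable = FALSE))
  d <- mean(x) - mean(y)
  vx <- var(x) / nx
  vy <- var(y) / ny
  if (vx + vy == 0) {
    return(list(t = 0, p = 1, mean_diff = d, df = nx + ny - 2,
                testable = d == 0))
  }
  t <- d / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  list(t = t, p = 2 * pt(-abs(t), df), mean_diff = d, df = df,
       testable = TRUE)
}

#' Test a TF's trans-activity via target vs non-target CSE
#'
#' Welch two-sample t-test on log2 CSE between the TF's target genes and all
#' other valid genes, for one (query, foreground) CSE table. A positive mean
#' difference means the foreground strain activates the TF's targets more
#' than the background strains do.
#'
#' @param cse a `cse_table` from [compute_cse()].
#' @param targets character vector of target gene ids.
#' @return A list: t, p, mean_diff (log2 CSE target minus non-target),
#'   mean_diff_cse (same on the CSE scale), df, n_target, n_nontarget,
#'   testable.
#' @export
tf_activity_test <- function(cse, targets) {
  ok <- cse$valid & is.finite(cse$log2_cse)
  is_t <- cse$gene %in% targets
  x <- cse$log2_cse[ok & is_t]
  y <- cse$log2_cse[ok & !is_t]
  w <- .welch(x, y)
  w$mean_diff_cse <- mean(cse$cse[ok & is_t]) - mean(cse$cse[ok & !is_t])
  w$n_target <- length(x)
  w$n_nontarget <- length(y)
  w
}

#' Consolidate per-query trans-activity tests into per-(TF, foreground) calls
#'
#' For each (TF, foreground strain) pair: runs the target/non-target Welch
#' test separately for each of the three query parents (for the consistency
#' requirement that all three mean differences share a sign) and once on the
#' three queries' CSE values pooled (one p per pair). Pooled p-values enter
#' a single Benjamini-Hochberg correction across all complete pairs; a pair
#' is significant when `q <= alpha` and consistent.
#'
#' @param cse_tables named list of `cse_table`s, one per (query, foreground)
#'   combination (any names; query/foreground are read from the tables).
#' @param targets_by_tf named list: TF -> target gene ids.
#' @param alpha BH false-discovery level (default 0.1).
#' @return data.frame of class `tf_activity_table`: tf, foreground, t, p,
#'   delta_log2_cse, delta_cse, q, consistent, direction, significant,
#'   n_target, plus per-query mean differences `d_q1..d_q3`.
#' @export
consolidate_activity <- function(cse_tables, targets_by_tf, alpha = 0.1) {
  meta <- do.call(rbind, lapply(cse_tables, function(cc)
    data.frame(query = cc$query[1L], foreground = cc$foreground[1L])))
  rows <- list()
  for (tf in names(targets_by_tf)) {
    tg <- targets_by_tf[[tf]]
    for (fg in unique(meta$foreground)) {
      idx <- which(meta$foreground == fg)
      if (length(idx) < 3L) next
      per_q <- lapply(idx, function(i) tf_activity_test(cse_tables[[i]], tg))
      dq <- vapply(per_q, function(r) r$mean_diff, numeric(1))
      pooled_tab <- do.call(rbind, cse_tables[idx])
      pooled <- tf_activity_test(pooled_tab, tg)
      complete <- all(vapply(per_q, function(r) isTRUE(r$testable),
                             logical(1))) && isTRUE(pooled$testable)
      rows[[length(rows) + 1L]] <- data.frame(
        tf = tf, foreground = fg, t = pooled$t, p = pooled$p,
        delta_log2_cse = pooled$mean_diff,
        delta_cse = pooled$mean_diff_cse,
        consistent = complete && (all(dq > 0) || all(dq < 0)),
        complete = complete,
        direction = if (isTRUE(pooled$mean_diff > 0)) "up" else "down",
        n_target = pooled$n_target,
        d_q1 = dq[1L], d_q2 = dq[2L], d_q3 = dq[3L])
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  in_family <- out$complete & !is.na(out$p)
  out$q[in_family] <- p.adjust(out$p[in_family], method = "BH")
  out$significant <- !is.na(out$q) & out$q <= alpha & out$consistent
  class(out) <- c("tf_activity_table", "data.frame")
  out
}

#' @export
print.tf_activity_table <- function(x, ...) {
  df <- as.data.frame(unclass(x), stringsAsFactors = FALSE)
  if (!all(c("significant", "q") %in% names(df))) {
    print.data.frame(df, ...)
    return(invisible(x))
  }
  cat(sprintf("tf_activity_table: %d (TF, foreground) pairs, %d significant\n",
              nrow(df), sum(df$significant)))
  sig <- df[df$significant, intersect(c("tf", "foreground", "direction",
                                        "q", "delta_cse"), names(df))]
  if (nrow(sig)) print.data.frame(sig, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Full trans-mapping stage
#'
#' Computes normalized allele expression, CSE for every (query, foreground)
#' ordered strain pair, per-TF target sets from motif scores, and the
#' consolidated per-(TF, foreground) activity table.
#'
#' @param x an [allele_counts()] covering all hybrids of the strain set.
#' @param motif_scores matrix gene x TF of promoter motif scores (e.g. mean
#'   across strains of [motif_score_max()]).
#' @param alpha BH level (default 0.1).
#' @param eps CSE pseudocount.
#' @param min_n,max_frac passed to [define_targets()].
#' @return A list of class `trans_map`: `activity` (the consolidated table),
#'   `cse` (list of per-(query, foreground) tables), `targets` (per TF).
#' @export
trans_map <- function(x, motif_scores, alpha = 0.1, eps = 0.5, min_n = 50,
                      max_frac = 0.10) {
  expr <- allele_expression(x)
  strains <- unique(sub("_in_.*", "", colnames(expr)))
  combos <- expand.grid(query = strains, foreground = strains,
                        stringsAsFactors = FALSE)
  combos <- combos[combos$query != combos$foreground, , drop = FALSE]
  cse_tables <- lapply(seq_len(nrow(combos)), function(i)
    compute_cse(expr, combos$query[i], combos$foreground[i], eps = eps))
  targets <- lapply(setNames(colnames(motif_scores), colnames(motif_scores)),
                    function(tf) define_targets(setNames(motif_scores[, tf],
                                                         rownames(motif_scores)),
                                                min_n = min_n,
                                                max_frac = max_frac))
  structure(list(activity = consolidate_activity(cse_tables, targets,
                                                 alpha = alpha),
                 cse = cse_tables, targets = targets, expr = expr),
            class = "trans_map")
}

#' @export
print.trans_map <- function(x, ...) {
  print(x$activity)
  invisible(x)
}
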