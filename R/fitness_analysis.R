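# Fitness scoring: log2-fold enrichment, the synonymous-control null,
# hit calling at mean + k*SD, and cross-condition pleiotropy summaries.

#' Log2-fold enrichment (fitness score)
#'
#' `fitness = log2( ((count_post + a) / total_post) /
#' ((count_pre + a) / total_pre) )` with pseudocount `a` (default 0.5).
#' At `a = 0` a zero count makes the score undefined; such entries are
#' returned as `NA` with a warning. The score is frequency-based, hence
#' invariant to sequencing depth, and antisymmetric under swapping the
#' pre and post samples (at `a = 0`).
#'
#' @param countPre,countPost Cassette read counts (vectorized).
#' @param totalPre,totalPost Per-sample total counts (> 0).
#' @param pseudocount Nonnegative pseudocount added to both counts.
#' @return Numeric vector of fitness scores.
#' @examples
#' log2Enrichment(50, 1000, 200, 1000, pseudocount = 0)  # 2
#' @export
log2Enrichment <- function(countPre, totalPre, countPost, totalPost,
                           pseudocount = 0.5) {
  stopifnot(all(totalPre > 0), all(totalPost > 0), pseudocount >= 0,
            all(countPre >= 0), all(countPost >= 0))
  f <- log2(((countPost + pseudocount) / totalPost) /
            ((countPre + pseudocount) / totalPre))
  bad <- !is.finite(f)
  if (any(bad)) {
    warning(sum(bad), " score(s) undefined (zero count with zero ",
            "pseudocount); reported as NA")
    f[bad] <- NA_real_
  }
  f
}

#' Per-cassette fitness table for one condition
#'
#' Joins a pre/post count pair with the design table and scores every
#' cassette by [log2Enrichment()]. Totals are the per-sample mapped
#' totals (sum of cassette counts).
#'
#' @param countTable A [CassetteCounts-class] holding both samples, or a
#'   list `list(pre = named counts, post = named counts)`.
#' @param design Design `data.frame` (from [cassetteDesign()]) supplying
#'   `cassette_id`, `gene`, `position`, `wt_aa`, `mut_aa`, `is_control`.
#' @param preSample,postSample Sample ids in `countTable`.
#' @param condition Condition label for the output rows.
#' @param pseudocount See [log2Enrichment()].
#' @return A `data.frame` with one row per cassette: design columns plus
#'   `condition`, `count_pre`, `count_post`, `fitness`.
#' @export
fitnessTable <- function(countTable, design, preSample = "pre",
                         postSample = "post", condition = "selection",
                         pseudocount = 0.5) {
  if (is(countTable, "CassetteCounts")) {
    cm <- cassetteCounts(countTable)
    stopifnot(all(c(preSample, postSample) %in% colnames(cm)))
    pre <- cm[, preSample]; post <- cm[, postSample]
  } else {
    pre <- countTable$pre; post <- countTable$post
  }
  ids <- design$cassette_id
  cPre <- ifelse(ids %in% names(pre), pre[ids], 0)
  cPost <- ifelse(ids %in% names(post), post[ids], 0)
  out <- data.frame(
    cassette_id = ids, gene = design$gene, position = design$position,
    wt_aa = design$wt_aa, mut_aa = design$mut_aa,
    is_control = design$is_control, condition = condition,
    count_pre = unname(cPre), count_post = unname(cPost),
    stringsAsFactors = FALSE)
  out$fitness <- log2Enrichment(out$count_pre, sum(pre), out$count_post,
                                sum(post), pseudocount)
  rownames(out) <- NULL
  out
}

#' Synonymous-control null model
#'
#' The synonymous controls define the null distribution of the log2
#' fitness change of effectively wild-type cells: their mean and sample
#' (n-1) standard deviation give the hit cutoff `mean + k * sd`
#' (default k = 2).
#'
#' @param fitTable Fitness table from [fitnessTable()].
#' @param condition Condition to calibrate (default: the table's single
#'   condition).
#' @param k Cutoff multiplier.
#' @return A [ScreenNull-class].
#' @export
synonymousNull <- function(fitTable, condition = NULL, k = 2) {
  if (is.null(condition)) {
    condition <- unique(fitTable$condition)
    if (length(condition) != 1L)
      stop("specify `condition`: table has ", length(condition))
  }
  ctrl <- fitTable$fitness[fitTable$condition == condition &
                           fitTable$is_control]
  ctrl <- ctrl[is.finite(ctrl)]
  if (length(ctrl) < 2L)
    stop("null not estimable: fewer than 2 finite control scores")
  mu <- mean(ctrl)
  sdv <- stats::sd(ctrl)
  new("ScreenNull", condition = condition, mean = mu, sd = sdv,
      k = as.numeric(k), cutoff = mu + k * sdv,
      nControls = length(ctrl))
}

#' Call enriched hits against the control null
#'
#' A variant is a hit iff its fitness is strictly greater than the
#' condition's cutoff (`mean + k * sd` of the synonymous controls).
#' Controls are never reported as hits. Conditions with no null model
#' are reported `not-assayed` (`hit = NA`) with a warning. Rows are
#' sorted by descending fitness within condition.
#'
#' @param fitTable Fitness table from [fitnessTable()] (one or more
#'   conditions).
#' @param nullModels A [ScreenNull-class] or a list of them (one per
#'   condition).
#' @return The fitness table with added `cutoff` and `hit` columns
#'   (logical; `NA` = not assayed), hit rows first within condition.
#' @export
callHits <- function(fitTable, nullModels) {
  if (is(nullModels, "ScreenNull")) nullModels <- list(nullModels)
  cuts <- stats::setNames(
    vapply(nullModels, nullCutoff, numeric(1)),
    vapply(nullModels, function(x) x@condition, character(1)))
  out <- fitTable
  out$cutoff <- unname(cuts[out$condition])
  missing <- unique(out$condition[is.na(out$cutoff)])
  if (length(missing))
    warning("no null model for condition(s): ",
            paste(missing, collapse = ", "), "; reported not-assayed")
  out$hit <- !out$is_control & !is.na(out$fitness) &
    out$fitness > out$cutoff
  out$hit[is.na(out$cutoff)] <- NA
  out <- out[order(out$condition, -xtfrm(out$fitness)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of controls above the cutoff (empirical FDR report)
#'
#' Diagnostic only: the fraction of synonymous controls whose fitness
#' exceeds the condition cutoff. Never alters hit calls.
#'
#' @param fitTable Fitness table.
#' @param nullModel A [ScreenNull-class].
#' @return Fraction in `[0, 1]`.
#' @export
controlExceedance <- function(fitTable, nullModel) {
  ctrl <- fitTable$fitness[fitTable$condition == nullModel@condition &
                           fitTable$is_control]
  ctrl <- ctrl[is.finite(ctrl)]
  mean(ctrl > nullCutoff(nullModel))
}

#' Cross-condition pleiotropy summary
#'
#' Builds the variant-by-condition matrix over the union of variants
#' seen in any condition: cells are `"hit"`, `"no-hit"` or
#' `"not-assayed"`, and the shared-hit list collects variants hit in at
#' least two conditions.
#'
#' @param hits A hit table from [callHits()] (possibly rbind-ed across
#'   conditions), or any `data.frame` with columns `gene`, `condition`,
#'   `hit` and either a `variant` label or `wt_aa`/`position`/`mut_aa`.
#' @return A list with `matrix` (wide `data.frame`, one row per variant,
#'   one status column per condition plus `fitness.<condition>` scores)
#'   and `shared` (`data.frame` of variants hit in >= 2 conditions).
#' @export
pleiotropyMatrix <- function(hits) {
  stopifnot(nrow(hits) >= 1L)
  if (is.null(hits$variant))
    hits$variant <- paste0(hits$gene, " ", hits$wt_aa, hits$position,
                           hits$mut_aa)
  if (!is.null(hits$is_control)) hits <- hits[!hits$is_control, ]
  conds <- sort(unique(hits$condition))
  vars <- unique(hits$variant)
  status <- matrix("not-assayed", length(vars), length(conds),
                   dimnames = list(vars, conds))
  score <- matrix(NA_real_, length(vars), length(conds),
                  dimnames = list(vars, conds))
  for (i in seq_len(nrow(hits))) {
    v <- hits$variant[i]; cn <- hits$condition[i]
    status[v, cn] <- if (is.na(hits$hit[i])) "not-assayed"
                     else if (hits$hit[i]) "hit" else "no-hit"
    if (!is.null(hits$fitness)) score[v, cn] <- hits$fitness[i]
  }
  wide <- data.frame(variant = vars, status, check.names = FALSE,
                     stringsAsFactors = FALSE)
  for (cn in conds) wide[[paste0("fitness.", cn)]] <- score[, cn]
  rownames(wide) <- NULL
  nHit <- rowSums(status == "hit")
  shared <- data.frame(
    variant = vars[nHit >= 2L],
    conditions = vapply(vars[nHit >= 2L], function(v)
      paste(conds[status[v, ] == "hit"], collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  rownames(shared) <- NULL
  list(matrix = wide, shared = shared)
}

#' Write fitness-analysis outputs
#'
#' @param hits Hit table from [callHits()].
#' @param nullModels List of [ScreenNull-class] (or one).
#' @param hitPath Hit table TSV path.
#' @param nullPath Null-model JSON path.
#' @export
writeFitnessResults <- function(hits, nullModels, hitPath, nullPath) {
  utils::write.table(hits, hitPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (is(nullModels, "ScreenNull")) nullModels <- list(nullModels)
  jsonlite::write_json(
    lapply(nullModels, function(n)
      list(condition = n@condition, mean = n@mean, sd = n@sd, k = n@k,
           cutoff = n@cutoff, n_controls = n@nControls)),
    nullPath, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(hitPath, nullPath))
}
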