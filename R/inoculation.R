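# Inoculation-test evaluation: ratio-to-control normalization across
# repeated batches, Welch's two-tailed t-test, and effect classification.

#' Convert seedling dry weights to ratios relative to the batch control
#'
#' Inoculation tests are repeated on different dates ("batches") with their
#' own control trays; dividing every dry weight by the mean control weight
#' of the same batch and tissue removes multiplicative batch effects
#' exactly.  Control seedlings are converted too, so each batch's control
#' group has mean ratio 1.
#'
#' @param records data frame with columns `isolate_id`, `batch`, `group`
#'   (`"treated"` or `"control"`), `shoot_mg`, `root_mg`; each
#'   (isolate, batch) must contain at least one control seedling.
#' @param tissues subset of `c("shoot", "root", "whole")`; whole = shoot +
#'   root.
#' @return long data frame (`isolate_id`, `batch`, `group`, `tissue`,
#'   `ratio`).
#' @export
ratios_to_control <- function(records, tissues = c("shoot", "root", "whole")) {
  tissues <- match.arg(tissues, several.ok = TRUE)
  need <- c("isolate_id", "batch", "group", "shoot_mg", "root_mg")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records lack column(s): ", paste(miss, collapse = ", "))
  if (any(records$shoot_mg <= 0) || any(records$root_mg <= 0))
    stop("dry weights must be positive")
  w <- list(shoot = records$shoot_mg, root = records$root_mg,
            whole = records$shoot_mg + records$root_mg)
  key <- interaction(records$isolate_id, records$batch, drop = TRUE)
  out <- list()
  has_ctrl <- tapply(records$group == "control", key, any)
  nocontrol <- names(has_ctrl)[is.na(has_ctrl) | !has_ctrl]
  if (length(nocontrol))
    stop("batch(es) without control seedlings: ",
         paste(nocontrol, collapse = ", "))
  for (tis in tissues) {
    ctrl_mean <- tapply(w[[tis]][records$group == "control"],
                        key[records$group == "control"], mean)
    out[[tis]] <- data.frame(
      isolate_id = records$isolate_id, batch = records$batch,
      group = records$group, tissue = tis,
      ratio = w[[tis]] / ctrl_mean[as.character(key)],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Welch's two-sample t-test (two-tailed)
#'
#' Thin wrapper around [stats::t.test()] with `var.equal = FALSE`
#' (Satterthwaite degrees of freedom).  The degenerate case of two
#' constant samples is resolved by convention: p = 1 when the means are
#' equal, p = 0 otherwise.
#'
#' @param a,b numeric samples of size >= 2.
#' @return list with `t`, `df` and `p` (two-tailed).
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 observations")
  if (sd(a) == 0 && sd(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (eq) 0 else Inf * sign(mean(a) - mean(b)),
                df = NA_real_, p = if (eq) 1 else 0))
  }
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Classify an inoculation effect
#'
#' Promoting: mean ratio above 1 with p below `alpha`; inhibiting: mean
#' ratio below 1 with p below `alpha`; otherwise neutral.  The
#' significance tier records whether p also clears `alpha_strong` (the
#' two-star level).
#'
#' @param mean_ratio mean treated/control dry-weight ratio.
#' @param p two-tailed p-value.
#' @param alpha significance level (default 0.05).
#' @param alpha_strong strong level (default 0.01).
#' @return list with `effect_class` (`"promoting"`, `"inhibiting"`,
#'   `"neutral"`) and `significance` (`"**"`, `"*"` or `""`).
#' @export
classify_effect <- function(mean_ratio, p, alpha = 0.05,
                            alpha_strong = 0.01) {
  cls <- if (p < alpha && mean_ratio > 1) "promoting"
         else if (p < alpha && mean_ratio < 1) "inhibiting"
         else "neutral"
  sig <- if (p < alpha_strong) "**" else if (p < alpha) "*" else ""
  if (cls == "neutral") sig <- ""
  list(effect_class = cls, significance = sig)
}

#' Evaluate inoculation tests per isolate
#'
#' Normalizes to batch controls, then compares the treated ratio sample to
#' the control ratio sample per isolate with Welch's two-tailed t-test
#' (`mode = "two_sample"`, the default) or the treated ratios against 1
#' (`mode = "one_sample"`).  `level = "batch"` aggregates ratios to batch
#' means before testing.
#'
#' @param records see [ratios_to_control()].
#' @param tissue `"whole"` (default), `"shoot"` or `"root"`.
#' @param alpha,alpha_strong significance levels.
#' @param mode `"two_sample"` or `"one_sample"`.
#' @param level `"seedling"` (default) or `"batch"`.
#' @return data frame, one row per isolate: `isolate_id`, `tissue`,
#'   `n_treated`, `n_control`, `mean_ratio`, `t`, `df`, `p`,
#'   `effect_class`, `significance`.  No multiple-testing correction is
#'   applied across isolates (a `note` attribute records this).
#' @export
evaluate_inoculation <- function(records, tissue = "whole",
                                 alpha = 0.05, alpha_strong = 0.01,
                                 mode = c("two_sample", "one_sample"),
                                 level = c("seedling", "batch")) {
  mode <- match.arg(mode)
  level <- match.arg(level)
  ratios <- ratios_to_control(records, tissues = tissue)
  if (level == "batch") {
    agg <- stats::aggregate(ratio ~ isolate_id + batch + group,
                            data = ratios, FUN = mean)
    ratios <- agg
  }
  isolates <- unique(ratios$isolate_id)
  rows <- lapply(isolates, function(iso) {
    tr <- ratios$ratio[ratios$isolate_id == iso & ratios$group == "treated"]
    ct <- ratios$ratio[ratios$isolate_id == iso & ratios$group == "control"]
    wt <- if (mode == "two_sample") welch_t(tr, ct) else {
      ht <- t.test(tr, mu = 1)
      list(t = unname(ht$statistic), df = unname(ht$parameter),
           p = ht$p.value)
    }
    cl <- classify_effect(mean(tr), wt$p, alpha, alpha_strong)
    data.frame(isolate_id = iso, tissue = tissue,
               n_treated = length(tr), n_control = length(ct),
               mean_ratio = mean(tr), t = wt$t, df = wt$df, p = wt$p,
               effect_class = cl$effect_class,
               significance = cl$significance, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "note") <-
    "p-values are per isolate; no multiple-testing correction is applied"
  out
}
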