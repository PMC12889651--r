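#' Build a screen table
#'
#' The substrate of the enrichment metrics: one row per ligand with its
#' score (higher = predicted binder) and its experimental label.
#'
#' @param ligand_id character ids, unique (subsample replicates relax
#'   this internally via a replicate index).
#' @param score numeric scores.
#' @param label `"binder"` / `"nonbinder"` per ligand.
#' @return data.frame of class `screen_table`.
#' @export
screen_table <- function(ligand_id, score, label) {
  n <- length(ligand_id)
  stopifnot(length(score) == n, length(label) == n)
  label <- as.character(label)
  if (!all(label %in% c("binder", "nonbinder"))) {
    stop("labels must be 'binder' or 'nonbinder'")
  }
  if (anyDuplicated(ligand_id)) stop("duplicate ligand_id in screen table")
  if (any(!is.finite(score))) stop("scores must be finite")
  structure(
    data.frame(ligand_id = as.character(ligand_id), score = as.numeric(score),
               label = label, stringsAsFactors = FALSE),
    class = c("screen_table", "data.frame")
  )
}

as_screen_table <- function(x) {
  if (inherits(x, "screen_table")) return(x)
  if (is.data.frame(x) && all(c("ligand_id", "score", "label") %in% names(x))) {
    return(screen_table(x$ligand_id, x$score, x$label))
  }
  stop("expected a screen table with columns ligand_id, score, label")
}

# deterministic ranking order: score descending, then ligand_id, then an
# optional replicate index (subsample duplicates)
screen_order <- function(tab) {
  rep_idx <- if ("replicate" %in% names(tab)) tab$replicate else rep(0L, nrow(tab))
  order(-tab$score, tab$ligand_id, rep_idx)
}

#' Label ligands by experimental pKi
#'
#' Compounds with pKi below `lower` are non-binders and those above `upper`
#' are binders; the ambiguous band in between is excluded so the two
#' classes stay pharmacologically distinct (defaults 5 and 6).
#'
#' @param pki numeric pKi value(s).
#' @param lower non-binder threshold (pKi < lower), default 5.
#' @param upper binder threshold (pKi > upper), default 6.
#' @return character vector in `{"binder", "nonbinder", "excluded"}`.
#' @examples
#' classify_by_pki(c(4.2, 5.5, 6.5))
#' @export
classify_by_pki <- function(pki, lower = 5, upper = 6) {
  stopifnot(lower <= upper)
  if (any(!is.finite(pki))) stop("pKi values must be finite")
  ifelse(pki < lower, "nonbinder", ifelse(pki > upper, "binder", "excluded"))
}

#' Hit rate of a screening library
#'
#' Fraction of binders among all ligands — the base rate that normalises
#' the enrichment factor (its EF100 term).
#'
#' @param tab a [screen_table()].
#' @return fraction in \[0, 1\].
#' @examples
#' tab <- screen_table(sprintf("L%02d", 1:41), rnorm(41),
#'                     rep(c("binder", "nonbinder"), c(14, 27)))
#' hit_rate(tab)  # 14/41 = 0.341
#' @export
hit_rate <- function(tab) {
  tab <- as_screen_table_lenient(tab)
  if (nrow(tab) == 0L) stop("empty screen table")
  mean(tab$label == "binder")
}

# accepts replicate-bearing tables from subsampling (duplicate ids allowed)
as_screen_table_lenient <- function(x) {
  if (is.data.frame(x) && all(c("ligand_id", "score", "label") %in% names(x))) {
    if (!all(x$label %in% c("binder", "nonbinder"))) {
      stop("labels must be 'binder' or 'nonbinder'")
    }
    return(x)
  }
  stop("expected a screen table with columns ligand_id, score, label")
}

#' Enrichment factor at a selection threshold
#'
#' \deqn{EF_{xx} = \frac{\mathrm{hits\ in\ top\ } xx\%}{xx\% \cdot N}
#'   \Big/ \frac{n_{binders}}{N}}
#' The top-xx% selection contains `ceil(xx/100 * N)` ligands (ranked by
#' score descending, ties by ligand id), but the denominator keeps the
#' exact fractional count `xx/100 * N`, so EF at 100% is exactly 1 for any
#' table. Values above 1 indicate enrichment over random selection.
#'
#' @param tab a screen table (replicate-bearing subsample tables allowed).
#' @param xx selection percentage in (0, 100\].
#' @return list of class `enrichment_result` with fields `xx`, `ef`,
#'   `n_selected`, `hits_in_selection`.
#' @examples
#' tab <- screen_table(sprintf("L%02d", 1:32), 32:1,
#'                     rep(c("binder", "nonbinder"), c(5, 27)))
#' ef_at(tab, 30)$ef  # 10/3: perfect ranking of a 5/32 screen
#' @export
ef_at <- function(tab, xx) {
  tab <- as_screen_table_lenient(tab)
  stopifnot(is.numeric(xx), length(xx) == 1L, xx > 0, xx <= 100)
  N <- nrow(tab)
  n_binders <- sum(tab$label == "binder")
  if (n_binders == 0L) stop("enrichment factor undefined: no binders in table")
  ord <- screen_order(tab)
  n_sel <- as.integer(ceiling(xx / 100 * N))
  hits <- sum(tab$label[ord][seq_len(n_sel)] == "binder")
  ef <- (hits / (xx / 100 * N)) / (n_binders / N)
  structure(list(xx = xx, ef = ef, n_selected = n_sel, hits_in_selection = hits),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("EF%g = %.4f (%d of top %d are hits)\n",
              x$xx, x$ef, x$hits_in_selection, x$n_selected))
  invisible(x)
}

#' BEDROC early-enrichment score
#'
#' Boltzmann-enhanced discrimination of ROC (Truchon & Bailly): ranks are
#' weighted by \eqn{e^{-\alpha r_i / N}}, so actives recovered early
#' dominate the score. First the robust initial enhancement
#' \deqn{RIE = \frac{\frac{1}{n}\sum_{i=1}^{n} e^{-\alpha r_i / N}}
#'   {\frac{1}{N}\frac{1 - e^{-\alpha}}{e^{\alpha/N} - 1}}}
#' over the ranks \eqn{r_i} of the \eqn{n} actives, then
#' \deqn{BEDROC = RIE \cdot \frac{R_a \sinh(\alpha/2)}
#'   {\cosh(\alpha/2) - \cosh(\alpha/2 - \alpha R_a)}
#'   + \frac{1}{1 - e^{\alpha(1 - R_a)}}}
#' with \eqn{R_a = n/N}. Bounded by \[0, 1\] up to the discrete-N
#' approximation; larger \eqn{\alpha} puts more weight on the earliest
#' ranks (\eqn{\alpha = 20} weights roughly the top 8%).
#'
#' @param tab a screen table (replicate-bearing tables allowed).
#' @param alpha early-recognition weight (> 0), default 20.
#' @return BEDROC score.
#' @export
bedroc <- function(tab, alpha = 20) {
  tab <- as_screen_table_lenient(tab)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0)
  N <- nrow(tab)
  ord <- screen_order(tab)
  ranks <- which(tab$label[ord] == "binder")
  n <- length(ranks)
  if (n == 0L) stop("BEDROC undefined: no binders in table")
  ra <- n / N
  rie <- mean(exp(-alpha * ranks / N)) /
    ((1 / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  rie * ra * sinh(alpha / 2) / (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra)) +
    1 / (1 - exp(alpha * (1 - ra)))
}

#' Binder subsampling with replacement
#'
#' Emulates a realistic virtual-screening hit rate from a binder-rich
#' benchmark: each repeat draws `k` binders with replacement (duplicates
#' kept as distinct rows sharing the ligand's score), keeps every
#' non-binder, and recomputes the enrichment metrics. Summaries are the
#' mean, median and percentile 2.5/97.5 interval across repeats.
#' Deterministic given `seed`.
#'
#' @param tab a [screen_table()] with at least one binder.
#' @param k binders drawn per repeat (>= 1), default 5.
#' @param n_repeats number of independent repeats, default 200.
#' @param xx_list EF selection percentages, default `c(10, 20, 30)`.
#' @param alpha_list BEDROC alphas, default `20`.
#' @param seed RNG seed.
#' @return data.frame with one row per metric: columns `metric`
#'   (`"EF"`/`"BEDROC"`), `param` (xx or alpha), `mean`, `median`, `lo`,
#'   `hi` (2.5/97.5 percentiles), `n_repeats`.
#' @export
subsample_enrichment <- function(tab, k = 5L, n_repeats = 200L,
                                 xx_list = c(10, 20, 30), alpha_list = 20,
                                 seed = 1L) {
  tab <- as_screen_table(tab)
  if (!is.numeric(k) || length(k) != 1L || k < 1) stop("`k` must be >= 1")
  k <- as.integer(k)
  stopifnot(n_repeats >= 1)
  binders <- tab[tab$label == "binder", , drop = FALSE]
  nonbinders <- tab[tab$label == "nonbinder", , drop = FALSE]
  if (nrow(binders) == 0L) stop("subsampling needs at least one binder")
  set.seed(as.integer(seed))
  n_metrics <- length(xx_list) + length(alpha_list)
  vals <- matrix(NA_real_, nrow = n_repeats, ncol = n_metrics)
  for (r in seq_len(n_repeats)) {
    idx <- sample.int(nrow(binders), k, replace = TRUE)
    sub <- rbind(
      cbind(binders[idx, , drop = FALSE], replicate = seq_len(k)),
      cbind(nonbinders, replicate = 0L)
    )
    vals[r, ] <- c(
      vapply(xx_list, function(xx) ef_at(sub, xx)$ef, numeric(1)),
      vapply(alpha_list, function(a) bedroc(sub, a), numeric(1))
    )
  }
  out <- data.frame(
    metric = rep(c("EF", "BEDROC"), c(length(xx_list), length(alpha_list))),
    param = c(xx_list, alpha_list),
    mean = colMeans(vals),
    median = apply(vals, 2, median),
    lo = apply(vals, 2, quantile, probs = 0.025, names = FALSE),
    hi = apply(vals, 2, quantile, probs = 0.975, names = FALSE),
    n_repeats = as.integer(n_repeats)
  )
  out
}

#' Read a score/label table from delimited text
#'
#' Accepts a header of either `ligand_id,score,label` or
#' `ligand_id,score,pki`; in the pKi form, ligands are labeled with
#' [classify_by_pki()] and the ambiguous band is dropped.
#'
#' @param path file path (comma-, tab- or whitespace-delimited; inferred
#'   from the header line).
#' @param lower,upper pKi thresholds passed to [classify_by_pki()].
#' @return a [screen_table()].
#' @export
read_screen_table <- function(path, lower = 5, upper = 6) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl(",", header)) "," else if (grepl("\t", header)) "\t" else ""
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("ligand_id", "score") %in% names(df))) {
    stop("expected columns ligand_id, score and one of label/pki")
  }
  if ("label" %in% names(df)) {
    return(screen_table(df$ligand_id, df$score, df$label))
  }
  if ("pki" %in% names(df)) {
    lab <- classify_by_pki(df$pki, lower, upper)
    keep <- lab != "excluded"
    return(screen_table(df$ligand_id[keep], df$score[keep], lab[keep]))
  }
  stop("expected a 'label' or 'pki' column")
}
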