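#' Terminal value of a c(t) series
#'
#' The stability readout of a single replica: c(t) evaluated at the final
#' time point of the series.
#'
#' @param series a [ct_series()].
#' @return c at the final time, kT.
#' @export
terminal_ct <- function(series) {
  if (!is.data.frame(series) || !all(c("time", "ct") %in% names(series))) {
    stop("expected a `ct_series` data.frame with columns time, ct")
  }
  if (nrow(series) == 0L) stop("empty c(t) series has no terminal value")
  series$ct[nrow(series)]
}

#' CTMD stability score of one ligand pose
#'
#' The score is the minimum over independent replicas of the terminal c(t):
#' the most pessimistic replica decides. A pose must withstand the tempered
#' bias in every replica to score high, which is what makes the minimum a
#' conservative stability proxy. Higher score = more stable pose =
#' predicted binder. A replica with no deposited hills contributes a
#' terminal c(t) of 0 (the estimator's floor).
#'
#' @param replicas a list of [hills()] objects (or a list of `ct_series`),
#'   one per independent replica.
#' @param ligand_id identifier for the ligand.
#' @param grid a [ct_grid()]; required when `replicas` are hill lists.
#' @param thermo a [thermo_params()]; required when `replicas` are hill
#'   lists.
#' @return an object of class `ligand_score`: list with `ligand_id`,
#'   `score` (kT) and `per_replica_terminal_ct`.
#' @export
ctmd_score <- function(replicas, ligand_id = "ligand", grid = NULL, thermo = NULL) {
  if (!is.list(replicas) || length(replicas) < 1L) {
    stop("`replicas` must be a non-empty list")
  }
  terminals <- vapply(seq_along(replicas), function(i) {
    r <- replicas[[i]]
    val <- tryCatch({
      if (is.data.frame(r) && all(c("time", "ct") %in% names(r))) {
        terminal_ct(r)
      } else {
        hl <- as_hills(r)
        if (nrow(hl) == 0L) 0 else ct_value(hl, Inf, grid, thermo)
      }
    }, error = function(e) {
      stop(sprintf("replica %d of ligand '%s' failed c(t) evaluation: %s",
                   i, ligand_id, conditionMessage(e)), call. = FALSE)
    })
    val
  }, numeric(1))
  structure(
    list(ligand_id = as.character(ligand_id),
         score = min(terminals),
         per_replica_terminal_ct = terminals),
    class = "ligand_score"
  )
}

#' @export
print.ligand_score <- function(x, ...) {
  cat(sprintf("ligand %s: CTMD score %.4f kT (min of %s)\n",
              x$ligand_id, x$score,
              paste(sprintf("%.4f", x$per_replica_terminal_ct), collapse = ", ")))
  invisible(x)
}

#' Rank ligands by CTMD score
#'
#' Descending by score; ties broken by ligand id ascending, so the ranking
#' is deterministic.
#'
#' @param scores a list of `ligand_score` objects, or a data.frame with
#'   columns `ligand_id` and `score`.
#' @return data.frame with columns `rank`, `ligand_id`, `score`.
#' @export
rank_ligands <- function(scores) {
  if (is.data.frame(scores)) {
    stopifnot(all(c("ligand_id", "score") %in% names(scores)))
    df <- data.frame(ligand_id = as.character(scores$ligand_id),
                     score = scores$score)
  } else {
    if (!is.list(scores) || length(scores) == 0L) stop("`scores` must be non-empty")
    df <- data.frame(
      ligand_id = vapply(scores, function(x) x$ligand_id, character(1)),
      score = vapply(scores, function(x) x$score, numeric(1))
    )
  }
  if (nrow(df) == 0L) stop("`scores` must be non-empty")
  if (anyDuplicated(df$ligand_id)) {
    stop(sprintf("duplicate ligand_id: %s",
                 paste(unique(df$ligand_id[duplicated(df$ligand_id)]), collapse = ", ")))
  }
  ord <- order(-df$score, df$ligand_id)
  out <- df[ord, , drop = FALSE]
  out <- data.frame(rank = seq_len(nrow(out)), ligand_id = out$ligand_id,
                    score = out$score, row.names = NULL)
  out
}
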