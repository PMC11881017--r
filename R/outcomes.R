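#' Reduce a scenario trajectory to its outcome record
#'
#' Computes the per-replicate outcome metrics from a [run_scenario()]
#' trajectory: persistence at the final census (habitat loss + the full
#' change period + the post-change period), time to extinction (first
#' post-loss generation with no survivors; censored when the population
#' persists), the fractions of the pre-loss population size and of the
#' pre-loss standing genetic variation remaining, mean per-individual
#' per-generation displacement over the post-loss period (non-movers
#' contribute 0), and the final phenotypic variance.
#'
#' @param trajectory A `sim_trajectory` from [run_scenario()].
#' @param properties Optional one-row data.frame of scenario properties
#'   (`delta_Be`, `delta_mu_e`, `l_hl`) carried onto the record.
#' @param landscape_id,scenario_id,replicate Identifiers carried onto the
#'   record.
#' @return One-row data.frame (an outcome record).
#' @export
score_trajectory <- function(trajectory, properties = NULL,
                             landscape_id = NA_integer_,
                             scenario_id = NA_integer_,
                             replicate = NA_integer_) {
  stopifnot(inherits(trajectory, "sim_trajectory"))
  cen <- trajectory$census
  pre <- trajectory$pre
  if (is.null(pre$n) || pre$n <= 0)
    stop("malformed trajectory: missing or empty pre-loss census", call. = FALSE)
  final_n <- cen$n_alive[nrow(cen)]
  persisted <- final_n > 0
  extinct_at <- which(cen$n_alive == 0)
  t_extinct <- if (length(extinct_at)) cen$post_gen[extinct_at[1]] else NA_integer_
  tot_moving <- sum(cen$n_moving)
  mu_d <- if (tot_moving > 0)
    sum(cen$mean_displacement * cen$n_moving) / tot_moving else 0
  rec <- data.frame(
    landscape_id = landscape_id, scenario_id = scenario_id,
    replicate = replicate, persisted = persisted,
    t_extinct = t_extinct,
    delta_n_i = final_n / pre$n,
    delta_n_a = if (pre$n_alleles > 0)
      cen$n_alleles[nrow(cen)] / pre$n_alleles else NA_real_,
    mu_d = mu_d,
    var_pheno = cen$var_phenotype[nrow(cen)],
    delta_e = trajectory$delta_e
  )
  if (!is.null(properties))
    for (v in c("delta_Be", "delta_mu_e", "l_hl"))
      if (v %in% names(properties)) rec[[v]] <- properties[[v]]
  rec
}

#' Aggregate replicate outcomes into persistence proportions
#'
#' @param records data.frame of outcome records ([score_trajectory()] rows).
#' @param by Character vector of grouping columns (default landscape and
#'   scenario, keeping the `delta_e` arm separate when present).
#' @return data.frame with one row per group: `persisted` (count),
#'   `trials`, `p_persist`, plus the group means of any scenario-property
#'   columns present.
#' @export
aggregate_persistence <- function(records,
                                  by = intersect(c("landscape_id", "scenario_id",
                                                   "delta_e"), names(records))) {
  stopifnot(nrow(records) >= 1, all(by %in% names(records)))
  key <- interaction(records[by], drop = TRUE)
  rows <- lapply(split(records, key), function(d) {
    out <- d[1, by, drop = FALSE]
    out$persisted <- sum(d$persisted)
    out$trials <- nrow(d)
    out$p_persist <- out$persisted / out$trials
    for (v in intersect(c("delta_Be", "delta_mu_e", "l_hl"), names(d)))
      out[[v]] <- mean(d[[v]])
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write outcome or aggregated tables as TSV
#'
#' @param x A data.frame.
#' @param path Output path.
#' @export
write_outcomes <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
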