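#' Screen OTUs as community-tolerance bioindicators
#'
#' Restricts to OTUs reaching a relative abundance of at least
#' `abundance_threshold` in at least one sample, computes the Spearman
#' rank correlation (average-rank ties) of each OTU's per-sample relative
#' abundance with both community trait indicators (logIC50 and pH_opt),
#' and classifies the OTU per trait as `positive` (rho >= rho_threshold),
#' `negative` (rho <= -rho_threshold) or `none`. OTUs with zero abundance
#' variance get rho 0 and a degenerate flag rather than a missing value,
#' so downstream counting stays total. No multiple-testing control is
#' applied: classification is by the fixed correlation threshold, not by
#' p-values.
#'
#' @param table a prepared [otu_table()] (rarefied, filtered).
#' @param profiles trait profiles with `sample_id`, `log_ic50`, `ph_opt`;
#'   samples must match the table.
#' @param abundance_threshold relative-abundance screen (fraction,
#'   default 0.01).
#' @param rho_threshold absolute Spearman correlation needed for a
#'   positive/negative call (default 0.5).
#' @return a data.frame of class `bioindicator_report`: `otu_id`,
#'   `taxonomy`, `max_rel_abundance`, `rho_salt`, `rho_ph`, `class_salt`,
#'   `class_ph`, `degenerate`. Empty (with a warning) if no OTU passes the
#'   abundance screen.
#' @export
screen_otus <- function(table, profiles, abundance_threshold = 0.01,
                        rho_threshold = 0.5) {
  stopifnot(inherits(table, "otu_table"),
            abundance_threshold > 0, abundance_threshold <= 1,
            rho_threshold > 0, rho_threshold <= 1)
  ids <- sample_ids(table)
  if (!all(ids %in% profiles$sample_id))
    stop("trait profiles missing for samples: ",
         paste(setdiff(ids, profiles$sample_id), collapse = ", "))
  prof <- profiles[match(ids, profiles$sample_id), ]
  rel <- relative_abundance(table)
  max_ab <- apply(rel, 2, max)
  keep <- max_ab >= abundance_threshold
  empty <- data.frame(otu_id = character(0), taxonomy = character(0),
                      max_rel_abundance = numeric(0),
                      rho_salt = numeric(0), rho_ph = numeric(0),
                      class_salt = character(0), class_ph = character(0),
                      degenerate = logical(0), stringsAsFactors = FALSE)
  if (!any(keep)) {
    warning("no OTU passes the relative-abundance screen")
    class(empty) <- c("bioindicator_report", "data.frame")
    return(empty)
  }
  rel <- rel[, keep, drop = FALSE]
  classify <- function(rho) {
    ifelse(rho >= rho_threshold, "positive",
           ifelse(rho <= -rho_threshold, "negative", "none"))
  }
  spearman_safe <- function(x, y) {
    if (var(x) == 0 || var(y) == 0) return(NA_real_)
    cor(x, y, method = "spearman")
  }
  rho_salt <- apply(rel, 2, spearman_safe, y = prof$log_ic50)
  rho_ph <- apply(rel, 2, spearman_safe, y = prof$ph_opt)
  degenerate <- is.na(rho_salt) | is.na(rho_ph)
  rho_salt[is.na(rho_salt)] <- 0
  rho_ph[is.na(rho_ph)] <- 0
  out <- data.frame(otu_id = colnames(rel),
                    taxonomy = unname(table$taxonomy[colnames(rel)]),
                    max_rel_abundance = unname(max_ab[keep]),
                    rho_salt = unname(rho_salt), rho_ph = unname(rho_ph),
                    class_salt = classify(unname(rho_salt)),
                    class_ph = classify(unname(rho_ph)),
                    degenerate = unname(degenerate),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("bioindicator_report", "data.frame")
  out
}

#' Bioindicator OTUs shared between two gradients
#'
#' Intersects the OTUs carrying a given classification for a given trait
#' in two bioindicator reports computed on disjoint sample sets (e.g. the
#' two gradients) that share an OTU namespace — the cross-gradient
#' consistency check for indicator taxa.
#'
#' @param report_a,report_b bioindicator reports from [screen_otus()].
#' @param trait `"salt"` or `"ph"`.
#' @param class `"positive"` or `"negative"`.
#' @return character vector of shared OTU ids.
#' @export
cross_gradient_overlap <- function(report_a, report_b,
                                   trait = c("salt", "ph"),
                                   class = c("positive", "negative")) {
  trait <- match.arg(trait)
  class <- match.arg(class)
  field <- paste0("class_", trait)
  intersect(report_a$otu_id[report_a[[field]] == class],
            report_b$otu_id[report_b[[field]] == class])
}

#' Joint classification table of salt versus pH bioindicators
#'
#' Cross-tabulates the per-OTU salt and pH classifications of a
#' bioindicator report into a 3x3 count table (positive / none /
#' negative). On gradients where salinity and pH are negatively
#' correlated, the salt-positive & pH-negative cell is expected to
#' dominate its mirror.
#'
#' @param report a non-empty bioindicator report.
#' @return a 3x3 `table`, rows = `class_salt`, columns = `class_ph`.
#' @export
cross_trait_table <- function(report) {
  if (nrow(report) == 0) stop("bioindicator report is empty")
  lv <- c("positive", "none", "negative")
  table(class_salt = factor(report$class_salt, levels = lv),
        class_ph = factor(report$class_ph, levels = lv))
}
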