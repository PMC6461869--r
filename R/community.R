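#' Construct an OTU count table
#'
#' A light container for an amplicon count matrix: non-negative integer
#' counts with samples as rows and OTUs as columns, plus a taxonomy string
#' per OTU (seven semicolon-separated ranks in the `k__...;p__...` style).
#'
#' @param counts samples x OTUs matrix of non-negative integers with row
#'   and column names.
#' @param taxonomy character vector of taxonomy strings, named by OTU id
#'   (or in column order).
#' @return an object of class `otu_table`.
#' @export
otu_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample row names and OTU column names")
  if (anyDuplicated(rownames(counts))) stop("sample ids must be unique")
  if (anyDuplicated(colnames(counts))) stop("OTU ids must be unique")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "double"
  if (is.null(taxonomy)) {
    taxonomy <- setNames(rep(NA_character_, ncol(counts)), colnames(counts))
  } else {
    if (!is.null(names(taxonomy))) {
      missing <- setdiff(colnames(counts), names(taxonomy))
      if (length(missing))
        stop("taxonomy missing for OTUs: ", paste(head(missing), collapse = ", "))
      taxonomy <- taxonomy[colnames(counts)]
    } else {
      stopifnot(length(taxonomy) == ncol(counts))
      names(taxonomy) <- colnames(counts)
    }
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %d samples x %d OTUs, total %d reads\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Sample ids and OTU ids of an OTU table
#' @param table an [otu_table()].
#' @return character vector of ids.
#' @export
sample_ids <- function(table) rownames(table$counts)

#' @rdname sample_ids
#' @export
otu_ids <- function(table) colnames(table$counts)

#' Remove samples below a sequencing-depth threshold
#'
#' Retains samples whose total read count is at least `min_reads`
#' (inclusive), preserving order.
#'
#' @param table an [otu_table()].
#' @param min_reads minimum total reads per sample.
#' @return a filtered `otu_table`.
#' @export
filter_samples_by_depth <- function(table, min_reads = 10000) {
  stopifnot(inherits(table, "otu_table"), min_reads >= 0)
  keep <- rowSums(table$counts) >= min_reads
  if (!any(keep)) stop("all samples fall below the depth threshold")
  otu_table(table$counts[keep, , drop = FALSE], table$taxonomy)
}

#' Rarefy an OTU table to even depth
#'
#' Subsamples every sample's reads without replacement to exactly `depth`
#' reads, correcting for differences in sequencing depth.
#'
#' @param table an [otu_table()] in which every sample has at least
#'   `depth` reads.
#' @param depth target reads per sample.
#' @param seed integer seed (subsampling is random but reproducible).
#' @return a rarefied `otu_table` with all row sums equal to `depth`.
#' @export
rarefy <- function(table, depth = 10000, seed) {
  stopifnot(inherits(table, "otu_table"), depth >= 1)
  short <- rowSums(table$counts) < depth
  if (any(short))
    stop("samples with fewer than ", depth, " reads cannot be rarefied: ",
         paste(rownames(table$counts)[short], collapse = ", "))
  set.seed(derive_seed(seed, 53L))
  # muffle vegan's "smallest count" heuristic: it fires on any table whose
  # rarest observed OTU has more than one read, which is the normal case here
  r <- withCallingHandlers(
    vegan::rrarefy(table$counts, depth),
    warning = function(w) {
      if (grepl("smallest count", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  r <- matrix(r, nrow(table$counts), ncol(table$counts),
              dimnames = dimnames(table$counts))
  otu_table(r, table$taxonomy)
}

#' Remove OTUs rarer than a total-count threshold
#'
#' Retains OTUs observed at least `min_total` times across all samples
#' (inclusive).
#'
#' @param table an [otu_table()].
#' @param min_total minimum total count across samples.
#' @return a filtered `otu_table`.
#' @export
filter_rare_otus <- function(table, min_total = 10) {
  stopifnot(inherits(table, "otu_table"), min_total >= 0)
  keep <- colSums(table$counts) >= min_total
  otu_table(table$counts[, keep, drop = FALSE], table$taxonomy[keep])
}

#' The standard preparation sequence for OTU tables
#'
#' Applies, in order: the sample-depth filter, rarefaction to even depth,
#' and the rare-OTU filter (rare-OTU totals are assessed on the rarefied
#' table). Counts of removed samples and OTUs at each step are recorded in
#' the `"prep_log"` attribute and reported via [message()].
#'
#' @param table an [otu_table()].
#' @param min_depth minimum reads for a sample to be kept.
#' @param rarefy_depth even depth to rarefy to.
#' @param min_otu_total minimum rarefied total for an OTU to be kept.
#' @param seed integer seed for rarefaction.
#' @param quiet suppress the log message.
#' @return the prepared `otu_table`, with attribute `"prep_log"`.
#' @export
prepare_otu_table <- function(table, min_depth = 10000,
                              rarefy_depth = 10000, min_otu_total = 10,
                              seed, quiet = FALSE) {
  n_samples <- nrow(table$counts); n_otus <- ncol(table$counts)
  t1 <- filter_samples_by_depth(table, min_depth)
  t2 <- rarefy(t1, rarefy_depth, seed = seed)
  t3 <- filter_rare_otus(t2, min_otu_total)
  log <- list(samples_in = n_samples,
              samples_removed = n_samples - nrow(t1$counts),
              samples_out = nrow(t3$counts),
              otus_in = n_otus,
              otus_removed = n_otus - ncol(t3$counts),
              otus_out = ncol(t3$counts),
              min_depth = min_depth, rarefy_depth = rarefy_depth,
              min_otu_total = min_otu_total)
  if (!quiet)
    message(sprintf(
      "removal of %d out of %d samples and %d of %d OTUs",
      log$samples_removed, log$samples_in, log$otus_removed, log$otus_in))
  attr(t3, "prep_log") <- log
  t3
}

#' Per-sample relative abundances
#'
#' @param table an [otu_table()] or counts matrix with no zero-sum rows.
#' @return a samples x OTUs matrix whose rows sum to 1.
#' @export
relative_abundance <- function(table) {
  counts <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  rs <- rowSums(counts)
  if (any(rs <= 0))
    stop("zero-sum samples: ", paste(rownames(counts)[rs <= 0], collapse = ", "))
  sweep(counts, 1, rs, "/")
}

#' Hellinger transformation
#'
#' Square root of relative abundances: each row of the result has unit
#' Euclidean norm, which makes Bray-Curtis and linear ordination well
#' behaved for sparse count data.
#'
#' @inheritParams relative_abundance
#' @return the Hellinger-transformed matrix.
#' @export
hellinger <- function(table) {
  counts <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  rs <- rowSums(counts)
  if (any(rs <= 0))
    stop("zero-sum samples: ", paste(rownames(counts)[rs <= 0], collapse = ", "))
  vegan::decostand(counts, method = "hellinger")
}

#' Shannon diversity per sample
#'
#' Shannon index H = -sum p_i log p_i over non-zero proportions, in natural
#' logarithms (nats).
#'
#' @inheritParams relative_abundance
#' @return named numeric vector of per-sample diversities.
#' @export
shannon <- function(table) {
  counts <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  rs <- rowSums(counts)
  if (any(rs <= 0))
    stop("zero-sum samples: ", paste(rownames(counts)[rs <= 0], collapse = ", "))
  vegan::diversity(counts, index = "shannon")
}

tax_ranks <- c(kingdom = "k__", phylum = "p__", class = "c__",
               order = "o__", family = "f__", genus = "g__",
               species = "s__")

#' Collapse an OTU table to a taxonomic rank
#'
#' Sums counts of OTUs sharing the same label at the requested rank
#' (parsed from `k__...;p__...`-style taxonomy strings); OTUs with no
#' assignment at that rank are pooled under `"Unassigned"`. `rank = "otu"`
#' returns the table unchanged.
#'
#' @param table an [otu_table()].
#' @param rank one of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, `"species"`, or `"otu"`.
#' @return an `otu_table` with one column per rank label.
#' @export
aggregate_taxonomy <- function(table, rank = "phylum") {
  stopifnot(inherits(table, "otu_table"))
  if (identical(rank, "otu")) return(table)
  if (!rank %in% names(tax_ranks))
    stop("unknown rank '", rank, "'; use one of ",
         paste(c(names(tax_ranks), "otu"), collapse = ", "))
  i <- match(rank, names(tax_ranks))
  labels <- vapply(strsplit(table$taxonomy, ";\\s*"), function(parts) {
    lab <- if (length(parts) >= i) parts[i] else ""
    lab <- sub(paste0("^", tax_ranks[rank]), "", lab)
    if (is.na(lab) || !nzchar(lab)) "Unassigned" else lab
  }, character(1))
  groups <- split(seq_along(labels), labels)
  agg <- sapply(groups, function(idx)
    rowSums(table$counts[, idx, drop = FALSE]))
  agg <- matrix(agg, nrow = nrow(table$counts),
                dimnames = list(rownames(table$counts), names(groups)))
  otu_table(agg, taxonomy = setNames(names(groups), names(groups)))
}

#' Read / write OTU tables as TSV
#'
#' The on-disk layout has one row per OTU: an `otu_id` column, one column
#' per sample, and a final `taxonomy` column. Round-trips losslessly.
#'
#' @param table an [otu_table()].
#' @param path file path.
#' @return `write_otu_table()` returns `path` invisibly;
#'   `read_otu_table()` returns an `otu_table`.
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "otu_table"))
  df <- data.frame(otu_id = colnames(table$counts),
                   t(table$counts),
                   taxonomy = unname(table$taxonomy),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_otu_table
#' @export
read_otu_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(names(df)[1] == "otu_id",
            names(df)[ncol(df)] == "taxonomy")
  counts <- t(as.matrix(df[, -c(1, ncol(df)), drop = FALSE]))
  colnames(counts) <- df$otu_id
  otu_table(counts, taxonomy = setNames(df$taxonomy, df$otu_id))
}
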