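#' OTU count table
#'
#' Light container for an amplicon OTU count matrix together with the sample
#' metadata the pipeline needs: a habitat (soil origin) label per sample and a
#' domain tag (prokaryote 16S or fungal ITS). Counts are stored samples x
#' OTUs; the on-disk TSV convention is the transpose (rows = OTUs, columns =
#' samples) with the OTU id in the first column.
#'
#' @param counts integer matrix, samples in rows, OTUs in columns; must have
#'   row (sample) and column (OTU) names.
#' @param habitat character/factor of length `nrow(counts)`: soil origin or
#'   habitat class per sample.
#' @param domain `"prokaryote"` or `"fungal"`.
#' @param taxonomy optional named character vector of lineages per OTU.
#' @return an object of class `otu_table`.
#' @export
otu_table <- function(counts, habitat, domain = c("prokaryote", "fungal"),
                      taxonomy = NULL) {
  domain <- match.arg(domain)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_data("`counts` needs sample (row) and OTU (column) names")
  if (anyDuplicated(rownames(counts))) stop_data("sample ids must be unique")
  if (anyDuplicated(colnames(counts))) stop_data("OTU ids must be unique")
  if (any(counts < 0) || any(counts != round(counts)))
    stop_data("counts must be non-negative integers")
  storage.mode(counts) <- "double"
  habitat <- as.character(habitat)
  if (length(habitat) != nrow(counts))
    stop_data("`habitat` must have one label per sample")
  structure(
    list(counts = counts, habitat = habitat, domain = domain,
         taxonomy = taxonomy),
    class = "otu_table"
  )
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %s: %d samples x %d OTUs, habitats: %s\n",
              x$domain, nrow(x$counts), ncol(x$counts),
              paste(unique(x$habitat), collapse = ", ")))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

n_otus <- function(x) ncol(x$counts)
otu_ids <- function(x) colnames(x$counts)
sample_ids <- function(x) rownames(x$counts)
sample_totals <- function(x) rowSums(x$counts)

#' Subset an OTU table by samples and/or OTUs, keeping metadata aligned
#' @param x an [otu_table].
#' @param samples,otus index vectors (positions, names or logicals accepted
#'   by matrix subsetting); `NULL` keeps everything.
#' @return the subset [otu_table].
#' @export
subset_otu_table <- function(x, samples = NULL, otus = NULL) {
  keep_s <- samples %||% seq_len(nrow(x$counts))
  keep_o <- otus %||% seq_len(ncol(x$counts))
  otu_table(x$counts[keep_s, keep_o, drop = FALSE],
            habitat = x$habitat[keep_s], domain = x$domain,
            taxonomy = x$taxonomy[colnames(x$counts)[keep_o]])
}

#' Read an OTU table from TSV
#'
#' Expects rows = OTUs, columns = samples, first column the OTU id (the usual
#' amplicon-pipeline export orientation).
#'
#' @param path TSV file path.
#' @param habitat habitat label per sample column (recycled if length 1), or a
#'   named vector keyed by sample id.
#' @inheritParams otu_table
#' @return an [otu_table].
#' @export
read_otu_table <- function(path, habitat, domain = c("prokaryote", "fungal")) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1L]])
  m <- t(as.matrix(raw[, -1L, drop = FALSE]))
  colnames(m) <- ids
  if (!is.null(names(habitat))) habitat <- habitat[rownames(m)]
  if (length(habitat) == 1L) habitat <- rep(habitat, nrow(m))
  otu_table(m, habitat = habitat, domain = domain)
}

#' Write an OTU table to TSV (rows = OTUs, columns = samples)
#' @param x an [otu_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path) {
  out <- data.frame(otu_id = otu_ids(x), t(x$counts), check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
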