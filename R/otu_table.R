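#' @useDynLib frontassembly, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Canonical metadata field order; merged sample ids join retained fields with "|"
# in this order.
METADATA_FIELDS <- c("season", "station", "depth", "size_fraction", "replicate")

SEASON_LEVELS <- c("March", "July", "September")
STATION_LEVELS <- c("O1", "O2", "F", "C1", "C2") # ocean -> coast
DEPTH_LEVELS <- c("surface", "DCM")
FRACTION_LEVELS <- c("micro", "nano", "pico")

#' Construct an OTU table
#'
#' The central community object: a samples x OTUs matrix of read counts,
#' per-sample metadata (season, station, depth, size fraction, replicate) and a
#' map from each OTU to its taxonomic reference (the unit at which traits are
#' annotated).
#'
#' @param counts numeric matrix, samples in rows, OTUs in columns. Row names are
#'   sample ids, column names OTU ids. Float input is accepted only if integral
#'   to within 1e-9.
#' @param metadata data.frame with one row per sample; must contain `sample_id`
#'   and any of season/station/depth/size_fraction/replicate.
#' @param taxref named character vector mapping OTU id to taxonomic reference.
#'   OTUs without an entry are mapped to `"unknown"`.
#' @param drop_empty_otus drop OTU columns whose total count is zero (with a
#'   warning). Validation requires no all-zero OTU after construction.
#' @return an object of class `otu_table`: list with elements `counts`,
#'   `metadata`, `taxref`.
#' @export
otu_table <- function(counts, metadata, taxref = NULL, drop_empty_otus = TRUE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample row names and OTU column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids in counts")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU ids in counts")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(abs(counts - round(counts)) > 1e-9))
    stop("counts must be integral (read counts); non-integral cell found")
  storage.mode(counts) <- "double"
  counts <- round(counts)

  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(metadata))
    stop("metadata must contain a sample_id column")
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata")
  missing <- setdiff(rownames(counts), metadata$sample_id)
  if (length(missing))
    stop("samples missing from metadata: ", paste(missing, collapse = ", "))
  metadata <- metadata[match(rownames(counts), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- metadata$sample_id
  metadata <- check_metadata_vocab(metadata)

  empty <- colSums(counts) == 0
  if (any(empty)) {
    if (drop_empty_otus) {
      warning(sum(empty), " OTU(s) with zero total count dropped: ",
              paste(utils::head(colnames(counts)[empty], 5), collapse = ", "),
              if (sum(empty) > 5) ", ...")
      counts <- counts[, !empty, drop = FALSE]
    } else {
      stop("all-zero OTU column(s) present")
    }
  }

  tr <- rep("unknown", ncol(counts))
  names(tr) <- colnames(counts)
  if (!is.null(taxref)) {
    hit <- intersect(names(taxref), colnames(counts))
    tr[hit] <- as.character(taxref[hit])
  }

  structure(list(counts = counts, metadata = metadata, taxref = tr),
            class = "otu_table")
}

check_metadata_vocab <- function(metadata) {
  chk <- function(col, levels) {
    if (!col %in% names(metadata)) return(invisible())
    vals <- unique(as.character(metadata[[col]]))
    bad <- setdiff(vals[!is.na(vals)], levels)
    if (length(bad))
      stop("metadata column '", col, "' has values outside its vocabulary: ",
           paste(bad, collapse = ", "))
  }
  chk("season", SEASON_LEVELS)
  chk("station", STATION_LEVELS)
  chk("depth", DEPTH_LEVELS)
  chk("size_fraction", FRACTION_LEVELS)
  if ("replicate" %in% names(metadata)) {
    r <- metadata$replicate
    if (any(!is.na(r) & (r < 1 | r != round(r))))
      stop("replicate must be a positive integer")
    metadata$replicate <- as.integer(metadata$replicate)
  }
  metadata
}

#' @export
print.otu_table <- function(x, ...) {
  cat("otu_table:", nrow(x$counts), "samples x", ncol(x$counts), "OTUs,",
      format(sum(x$counts), big.mark = ","), "reads\n")
  meta <- intersect(METADATA_FIELDS, names(x$metadata))
  if (length(meta)) cat("metadata fields:", paste(meta, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Number of samples / OTUs
#' @param x an `otu_table`
#' @export
n_samples <- function(x) nrow(x$counts)

#' @rdname n_samples
#' @export
n_otus <- function(x) ncol(x$counts)

#' Subset an OTU table
#'
#' @param x an `otu_table`
#' @param samples,otus character or logical/integer index vectors; `NULL` keeps
#'   everything.
#' @param drop_empty_otus drop OTUs that become all-zero after subsetting.
#' @export
subset_otu_table <- function(x, samples = NULL, otus = NULL,
                             drop_empty_otus = FALSE) {
  counts <- x$counts
  if (!is.null(samples)) counts <- counts[samples, , drop = FALSE]
  if (!is.null(otus)) counts <- counts[, otus, drop = FALSE]
  keep <- rep(TRUE, ncol(counts))
  if (drop_empty_otus) keep <- colSums(counts) > 0
  counts <- counts[, keep, drop = FALSE]
  structure(list(counts = counts,
                 metadata = x$metadata[rownames(counts), , drop = FALSE],
                 taxref = x$taxref[colnames(counts)]),
            class = "otu_table")
}

#' Read an OTU count table and its sample metadata
#'
#' The TSV orientation (samples x OTUs or OTUs x samples) is auto-detected: a
#' first header cell of `otu_id` means OTUs in rows, `sample_id` means samples
#' in rows; otherwise orientation is resolved by matching ids against the
#' metadata. OTUs with zero total count are dropped with a warning.
#'
#' @param path tab-delimited count table with a header row; first column holds
#'   the row ids.
#' @param metadata_path CSV with one row per `sample_id`.
#' @param taxref_path optional CSV with columns `otu_id,taxref`.
#' @return an [otu_table()].
#' @export
read_otu_table <- function(path, metadata_path, taxref_path = NULL) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("count table needs an id column and at least one data column")
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids))
    stop("duplicate row ids in count table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  mat <- as.matrix(raw[, -1, drop = FALSE])
  for (j in seq_len(ncol(mat))) {
    v <- suppressWarnings(as.numeric(mat[, j]))
    bad <- which(is.na(v) & !is.na(mat[, j]) & nzchar(mat[, j]))
    if (length(bad))
      stop("malformed numeric cell at row '", ids[bad[1]], "', column '",
           colnames(mat)[j], "'")
  }
  storage.mode(mat) <- "double"
  rownames(mat) <- ids

  metadata <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  sentinel <- tolower(names(raw)[1])
  orient_otu_rows <-
    if (sentinel %in% c("otu_id", "otu")) TRUE
    else if (sentinel %in% c("sample_id", "sample")) FALSE
    else mean(colnames(mat) %in% metadata$sample_id) >=
         mean(rownames(mat) %in% metadata$sample_id)
  if (orient_otu_rows) mat <- t(mat)

  taxref <- NULL
  if (!is.null(taxref_path)) {
    tr <- utils::read.csv(taxref_path, stringsAsFactors = FALSE)
    taxref <- stats::setNames(as.character(tr$taxref), tr$otu_id)
  }
  otu_table(mat, metadata, taxref = taxref)
}

#' Write an OTU table
#'
#' Writes `<stem>.tsv` (samples x OTUs counts), `<stem>_metadata.csv` and
#' `<stem>_taxref.csv`; [read_otu_table()] round-trips them losslessly.
#'
#' @param x an `otu_table`
#' @param stem path prefix, without extension
#' @return invisibly, the paths written
#' @export
write_otu_table <- function(x, stem) {
  counts_path <- paste0(stem, ".tsv")
  df <- data.frame(sample_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta_path <- paste0(stem, "_metadata.csv")
  utils::write.csv(x$metadata, meta_path, row.names = FALSE, quote = FALSE)
  tax_path <- paste0(stem, "_taxref.csv")
  utils::write.csv(data.frame(otu_id = names(x$taxref), taxref = unname(x$taxref)),
                   tax_path, row.names = FALSE, quote = FALSE)
  invisible(c(counts = counts_path, metadata = meta_path, taxref = tax_path))
}

#' Merge samples over metadata fields
#'
#' Sums counts within groups of samples that agree on every *retained* metadata
#' field, collapsing over the `keys` fields (e.g. `keys = c("replicate",
#' "depth", "size_fraction")` yields one sample per season x station). New
#' sample ids are deterministic `"|"`-joins of the retained field values in the
#' fixed order season, station, depth, size_fraction, replicate.
#'
#' @param table an `otu_table`
#' @param keys character vector, subset of
#'   `c("season","station","depth","size_fraction","replicate")`
#' @return an `otu_table` with one sample per group
#' @export
merge_samples <- function(table, keys) {
  if (length(keys) == 0) stop("keys must name at least one metadata field")
  bad <- setdiff(keys, METADATA_FIELDS)
  if (length(bad)) stop("unknown metadata field(s): ", paste(bad, collapse = ", "))
  retained <- setdiff(intersect(METADATA_FIELDS, names(table$metadata)), keys)
  if (length(retained) == 0) {
    grp <- rep("all", n_samples(table))
  } else {
    vals <- lapply(retained, function(f) as.character(table$metadata[[f]]))
    grp <- do.call(paste, c(vals, sep = "|"))
  }
  counts <- rowsum(table$counts, grp)
  # one metadata row per group, retained fields only
  first <- !duplicated(grp)
  meta <- table$metadata[first, retained, drop = FALSE]
  meta$sample_id <- grp[first]
  meta <- meta[match(rownames(counts), meta$sample_id), , drop = FALSE]
  meta <- meta[, c("sample_id", retained), drop = FALSE]
  rownames(meta) <- meta$sample_id
  structure(list(counts = counts, metadata = meta, taxref = table$taxref),
            class = "otu_table")
}

#' Presence (incidence) matrix of an OTU table
#' @param table an `otu_table`
#' @return logical matrix, samples x OTUs
#' @export
presence_matrix <- function(table) table$counts > 0
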