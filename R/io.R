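# Readers/writers for the remaining inputs (tree, traits, environment) and a
# generic result writer. All tabular output is TSV/CSV, nested results JSON,
# trees Newick: text formats only, lossless round-trips.

TRAIT_COLUMNS <- c("SizeMin", "SizeMax", "Cell Cover", "Cell Shape",
                   "Cell Symmetry", "Cell Polarity", "Ingestion method",
                   "Symbiosis type", "Presence of Spicule", "Coloniality",
                   "Motility", "Resting Stage")
TRAIT_NUMERIC <- c("SizeMin", "SizeMax")

#' Read a rooted phylogeny of OTUs from Newick
#'
#' @param path Newick file; branch lengths required, unlabeled internal nodes
#'   allowed.
#' @return an [ape::phylo] object with unique tip labels
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) {
    bad <- which(is.na(tree$edge.length))[1]
    stop("missing branch length on edge ", tree$edge[bad, 1], "->", tree$edge[bad, 2])
  }
  if (any(tree$edge.length < 0)) stop("negative branch length")
  tree
}

#' Write a phylogeny to Newick
#' @param tree an `ape::phylo`
#' @param path output file
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a trait table
#'
#' CSV with a `taxref` id column, the 12 morphological/trophic trait columns
#' (SizeMin and SizeMax numeric in micrometres, the rest categorical or binary)
#' and a logical `obligate_phototroph` column. Empty cells are missing values.
#'
#' @param path CSV file
#' @return data.frame with row names = taxref, traits as character/numeric and
#'   `obligate_phototroph` logical
#' @export
read_traits <- function(path) {
  tr <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (!"taxref" %in% names(tr)) stop("trait table needs a 'taxref' column")
  if (anyDuplicated(tr$taxref)) stop("duplicate taxref in trait table")
  rownames(tr) <- tr$taxref
  for (col in TRAIT_NUMERIC) if (col %in% names(tr)) tr[[col]] <- as.numeric(tr[[col]])
  if ("obligate_phototroph" %in% names(tr))
    tr$obligate_phototroph <- as.logical(tr$obligate_phototroph)
  both <- !is.na(tr$SizeMin) & !is.na(tr$SizeMax)
  if (any(both & tr$SizeMin > tr$SizeMax))
    stop("SizeMin > SizeMax for: ",
         paste(utils::head(tr$taxref[both & tr$SizeMin > tr$SizeMax], 5), collapse = ", "))
  tr
}

#' Write a trait table
#' @param traits data.frame as returned by [read_traits()]
#' @param path CSV output path
#' @export
write_traits <- function(traits, path) {
  utils::write.csv(traits, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a sample x environment table
#'
#' @param path CSV with a `sample_id` column and numeric environmental columns
#'   (temperature, NOx, ammonium, silicate, PAR, ...).
#' @return data.frame with row names = sample_id
#' @export
read_env <- function(path) {
  env <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(env)) stop("environment table needs a 'sample_id' column")
  if (anyDuplicated(env$sample_id)) stop("duplicate sample_id in environment table")
  rownames(env) <- env$sample_id
  num <- setdiff(names(env), "sample_id")
  conc <- intersect(c("NOx", "ammonium", "silicate", "PAR"), num)
  for (col in conc) if (any(env[[col]] < 0, na.rm = TRUE))
    stop("negative concentration in column ", col)
  env
}

#' Validate a labelled distance matrix
#'
#' @param m square numeric matrix with identical row and column labels
#' @param tol symmetry tolerance
#' @return the matrix, symmetrized exactly
#' @export
as_dist_matrix <- function(m, tol = 1e-12) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (is.null(rownames(m))) stop("distance matrix must be labelled")
  if (!identical(rownames(m), colnames(m))) stop("row/column labels differ")
  if (max(abs(m - t(m))) > tol) stop("matrix not symmetric within ", tol)
  if (any(diag(m) != 0)) stop("nonzero diagonal")
  if (any(m < 0)) stop("negative distances")
  (m + t(m)) / 2
}

#' Write / read a distance matrix as TSV
#' @param m labelled symmetric matrix
#' @param path TSV path
#' @export
write_dist_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dist_matrix
#' @export
read_dist_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  as_dist_matrix(m, tol = 1e-8)
}

#' Write an analysis result to disk
#'
#' Dispatches on result type: matrices and data.frames go to TSV, connectivity
#' networks to an edge-list TSV, nested lists to JSON. Output is bit-stable for
#' fixed inputs.
#'
#' @param obj result object
#' @param path output file
#' @export
write_results <- function(obj, path) {
  if (inherits(obj, "connectivity_network")) {
    utils::write.table(obj$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (is.matrix(obj)) {
    write_dist_matrix(obj, path)
  } else if (is.data.frame(obj)) {
    utils::write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (is.list(obj)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    stop("no writer for objects of class ", paste(class(obj), collapse = "/"))
  }
  invisible(path)
}
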