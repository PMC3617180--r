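#' Read landmark configurations from a TPS file
#'
#' Parses the TPS dialect produced by the tpsDig family of digitizers: each
#' record starts with an `LM=k` line followed by `k` whitespace-separated
#' `x y` coordinate rows; optional `SCALE=s` (multiplies the coordinates),
#' `ID=` and `IMAGE=` lines are honoured and any other `KEY=value` line is
#' ignored. Coordinates are 2D (buccal-view convention: x increases
#' anteriorly, y dorsally).
#'
#' @param path path to a TPS file.
#' @return a [shape_dataset()] with one specimen per TPS record, in file
#'   order; centroid sizes are computed from the scaled coordinates.
#'   Specimen ids come from `ID=` lines (falling back to `IMAGE=`, then to
#'   the record number).
#' @seealso [write_tps()]
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) stop("TPS file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  i <- 1L
  n_lines <- length(lines)
  while (i <= n_lines) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) { i <- i + 1L; next }
    if (!grepl("^LM\\s*=", ln, ignore.case = TRUE))
      stop(sprintf("line %d: expected 'LM=' record header, got '%s'", i, ln))
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", ln,
                                         ignore.case = TRUE)))
    if (is.na(k) || k < 1L)
      stop(sprintf("line %d: invalid landmark count in '%s'", i, ln))
    i <- i + 1L
    coords <- matrix(NA_real_, k, 2)
    got <- 0L
    while (got < k) {
      if (i > n_lines)
        stop(sprintf("record ending at line %d: expected %d coordinate rows, found %d",
                     n_lines, k, got))
      ln <- trimws(lines[i])
      if (!nzchar(ln)) { i <- i + 1L; next }
      parts <- strsplit(ln, "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(parts))
      if (length(vals) != 2L || anyNA(vals))
        stop(sprintf("line %d: expected two numeric coordinates, got '%s'", i, ln))
      got <- got + 1L
      coords[got, ] <- vals
      i <- i + 1L
    }
    id <- NA_character_; image <- NA_character_; scale <- NA_real_
    while (i <= n_lines) {
      ln <- trimws(lines[i])
      if (!nzchar(ln)) { i <- i + 1L; next }
      if (grepl("^LM\\s*=", ln, ignore.case = TRUE)) break
      if (!grepl("^[A-Za-z][A-Za-z0-9_]*\\s*=", ln))
        stop(sprintf("line %d: unexpected content '%s' between TPS records", i, ln))
      key <- toupper(trimws(sub("=.*$", "", ln)))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (key == "ID") id <- val
      else if (key == "IMAGE") image <- val
      else if (key == "SCALE") {
        scale <- suppressWarnings(as.numeric(val))
        if (is.na(scale) || scale <= 0)
          stop(sprintf("line %d: invalid SCALE value '%s'", i, val))
      } # other KEY=value lines ignored
      i <- i + 1L
    }
    if (!is.na(scale)) coords <- coords * scale
    recs[[length(recs) + 1L]] <- list(coords = coords, id = id, image = image)
  }
  if (!length(recs)) stop("no TPS records found in ", path)
  ks <- vapply(recs, function(r) nrow(r$coords), integer(1))
  if (length(unique(ks)) != 1L) {
    bad <- which(ks != ks[1])[1]
    stop(sprintf("inconsistent landmark counts: record %d has LM=%d but record 1 has LM=%d",
                 bad, ks[bad], ks[1]))
  }
  ids <- vapply(seq_along(recs), function(j) {
    r <- recs[[j]]
    if (!is.na(r$id) && nzchar(r$id)) r$id
    else if (!is.na(r$image) && nzchar(r$image)) r$image
    else sprintf("specimen_%d", j)
  }, character(1))
  coords <- array(unlist(lapply(recs, function(r) r$coords)),
                  dim = c(ks[1], 2, length(recs)))
  shape_dataset(coords, ids)
}

#' Write a shape dataset to a TPS file
#'
#' One `LM=k` record per specimen, in dataset order, with an `ID=` line
#' carrying the specimen id. Coordinates are written unscaled at full
#' double precision, so [read_tps()] round-trips them to better than 1e-9.
#'
#' @param dataset a [shape_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(dataset, path) {
  stopifnot(inherits(dataset, "shape_dataset"))
  if (dataset$n < 1L) stop("refusing to write an empty TPS file")
  out <- character(0)
  for (j in seq_len(dataset$n)) {
    m <- dataset$coords[, , j]
    out <- c(out,
             sprintf("LM=%d", dataset$k),
             sprintf("%.17g %.17g", m[, 1], m[, 2]),
             sprintf("ID=%s", dataset$specimen_id[j]))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a phylogeny and reconcile it with the analysis taxa
#'
#' Reads a rooted topology from newick or a NEXUS TREES block (detected by
#' the `#NEXUS` header) and discards all branch lengths, replacing them
#' with 1: the comparative analyses here use topology only. Tip labels are
#' whitespace-trimmed and matched case-sensitively against `taxa`; any
#' mismatch in either direction is an error listing the offending names.
#'
#' @param path newick or NEXUS file.
#' @param taxa character vector of analysis taxon names the tree must
#'   cover exactly (one tip per taxon). `NULL` skips reconciliation.
#' @return an [ape::read.tree()]-style `phylo` object with all branch
#'   lengths equal to 1.
#' @export
read_tree <- function(path, taxa = NULL) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  first <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
  tr <- if (length(first) && startsWith(first, "#NEXUS"))
    ape::read.nexus(path) else ape::read.tree(path)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) > 1L)
      warning("file contains ", length(tr), " trees; using the first")
    tr <- tr[[1]]
  }
  if (!inherits(tr, "phylo")) stop("could not parse a tree from ", path)
  tr$tip.label <- trimws(tr$tip.label)
  tr$edge.length <- rep(1, nrow(tr$edge))
  if (!is.null(taxa)) {
    taxa <- trimws(taxa)
    missing_tips <- setdiff(taxa, tr$tip.label)
    extra_tips <- setdiff(tr$tip.label, taxa)
    if (length(missing_tips) || length(extra_tips))
      stop(sprintf(
        "tree/taxa mismatch: taxa absent from tree: {%s}; tree tips not in taxa: {%s}",
        paste(missing_tips, collapse = ", "),
        paste(extra_tips, collapse = ", ")))
    if (any(duplicated(tr$tip.label)))
      stop("tree tip labels are not unique")
  }
  tr
}

#' Attach dietary and locomotor groups from a delimited table
#'
#' The table (tab- or comma-delimited, with a header) must contain a
#' `specimen_id` or `taxon` column plus `diet` and/or `locomotion` columns
#' drawn from [DIET_LEVELS] / [LOCOMOTION_LEVELS]. A `taxon` key labels
#' every specimen of that taxon. Specimens absent from the table keep (or
#' are set to) `"ungrouped"` — fossils and taxa of unknown ecology stay in
#' the dataset but never enter group-based fits.
#'
#' @param path path to the delimited table.
#' @param dataset a [shape_dataset()].
#' @return the dataset with `diet`/`locomotion` labels attached.
#' @export
read_groups <- function(path, dataset) {
  stopifnot(inherits(dataset, "shape_dataset"))
  if (!file.exists(path)) stop("groups table not found: ", path)
  header <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, strip.white = TRUE)
  names(tab) <- tolower(trimws(names(tab)))
  key <- if ("specimen_id" %in% names(tab)) "specimen_id"
         else if ("taxon" %in% names(tab)) "taxon"
         else stop("groups table needs a 'specimen_id' or 'taxon' column")
  if (!any(c("diet", "locomotion") %in% names(tab)))
    warning("groups table has no 'diet' or 'locomotion' column; ",
            "only taxon assignments attached")
  tab[[key]] <- trimws(as.character(tab[[key]]))
  if (any(duplicated(tab[[key]])))
    stop("duplicated keys in groups table: ",
         paste(unique(tab[[key]][duplicated(tab[[key]])]), collapse = ", "))
  idx <- match(dataset[[key]], tab[[key]])
  if (key == "specimen_id" && "taxon" %in% names(tab)) {
    tx <- trimws(as.character(tab$taxon))
    dataset$taxon <- ifelse(is.na(idx), dataset$taxon, tx[idx])
  }
  for (col in intersect(c("diet", "locomotion"), names(tab))) {
    vals <- trimws(as.character(tab[[col]]))
    check_vocab(vals, if (col == "diet") DIET_LEVELS else LOCOMOTION_LEVELS, col)
    new <- ifelse(is.na(idx), "ungrouped", vals[idx])
    dataset[[col]] <- new
  }
  dataset
}

#' Write a specimen table
#'
#' Tab-delimited, one row per specimen with its taxon, diet and
#' locomotion, suitable for [read_groups()].
#'
#' @param dataset a [shape_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_groups <- function(dataset, path) {
  stopifnot(inherits(dataset, "shape_dataset"))
  tab <- data.frame(specimen_id = dataset$specimen_id,
                    taxon = dataset$taxon,
                    diet = dataset$diet,
                    locomotion = dataset$locomotion)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check that a dataset, tree and groups agree
#'
#' Runs the reconciliation used by the pipeline: uniform landmark count,
#' one tree tip per taxon, labels within vocabulary.
#'
#' @param dataset a [shape_dataset()].
#' @param tree optional `phylo` covering the dataset taxa.
#' @return `TRUE` invisibly; otherwise an error describing the mismatch.
#' @export
validate_dataset <- function(dataset, tree = NULL) {
  stopifnot(inherits(dataset, "shape_dataset"))
  check_vocab(dataset$diet, DIET_LEVELS, "diet")
  check_vocab(dataset$locomotion, LOCOMOTION_LEVELS, "locomotion")
  if (!is.null(tree)) {
    taxa <- unique(dataset$taxon)
    missing_tips <- setdiff(taxa, tree$tip.label)
    extra_tips <- setdiff(tree$tip.label, taxa)
    if (length(missing_tips) || length(extra_tips))
      stop(sprintf(
        "tree/taxa mismatch: taxa absent from tree: {%s}; tree tips not in taxa: {%s}",
        paste(missing_tips, collapse = ", "),
        paste(extra_tips, collapse = ", ")))
  }
  invisible(TRUE)
}
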