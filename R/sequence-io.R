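#' Read and clean a multi-FASTA file of DNA sequences
#'
#' Parses a FASTA file and normalises each record to the four-letter DNA
#' alphabet: residues are upper-cased, `U` is mapped to `T` (RNA input), and
#' every other symbol (ambiguity codes such as N/Y/M, gap characters,
#' stray whitespace) is removed. Removed positions act as *adjacency
#' breaks*: a dinucleotide pair is only ever counted downstream if the two
#' residues were literally adjacent in the original sequence. Internally
#' each record is therefore stored as the run of contiguous A/C/G/T
#' segments it decomposes into.
#'
#' @param path Path to a FASTA file (headers start with `>`).
#' @return An object of class `fi_dataset`: a list of records, each a list
#'   with `id` (header up to the first whitespace) and `segments` (character
#'   vector of contiguous A/C/G/T runs).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACNGT", ">s2", "acgu"), fa)
#' ds <- read_fasta(fa)
#' dataset_residues(ds)
#' @seealso [dataset()] to build one in code, [distance_matrix()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dataset(setNames(as.character(set), ids))
}

#' Build a cleaned dataset from named sequence strings
#'
#' Applies the same cleaning rules as [read_fasta()] to in-memory sequences.
#'
#' @param sequences Named character vector (names are record ids) of raw
#'   residue strings; may contain lower case, `U`, and ambiguity codes.
#' @return An `fi_dataset` object.
#' @export
dataset <- function(sequences) {
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids))) stop("every sequence needs a non-empty id")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  records <- lapply(seq_along(sequences), function(i) {
    segs <- clean_residues(sequences[[i]])
    if (sum(nchar(segs)) < 2L) {
      stop("record '", ids[[i]], "' has fewer than 2 usable residues")
    }
    list(id = ids[[i]], segments = segs)
  })
  structure(records, class = "fi_dataset")
}

# Upper-case, U->T, then split on any non-ACGT run so that removed symbols
# break adjacency; zero-length segments are dropped.
clean_residues <- function(x) {
  x <- chartr("u", "T", toupper(x))
  x <- chartr("U", "T", x)
  segs <- strsplit(x, "[^ATGC]+")[[1]]
  segs[nzchar(segs)]
}

#' @export
print.fi_dataset <- function(x, ...) {
  cat("fi_dataset with", length(x), "sequences\n")
  for (r in head(x, 10L)) {
    cat(sprintf("  %-20s %8d bp  (%d segment%s)\n", r$id, sum(nchar(r$segments)),
                length(r$segments), if (length(r$segments) == 1L) "" else "s"))
  }
  if (length(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' Record ids / cleaned residues of a dataset
#' @param x An `fi_dataset`.
#' @return `dataset_ids()`: character vector of ids. `dataset_residues()`:
#'   named character vector of cleaned residue strings (segments
#'   concatenated; adjacency breaks are not recoverable from this view).
#' @export
dataset_ids <- function(x) vapply(x, `[[`, character(1), "id")

#' @rdname dataset_ids
#' @export
dataset_residues <- function(x) {
  setNames(vapply(x, function(r) paste(r$segments, collapse = ""), character(1)),
           dataset_ids(x))
}

#' Write a dataset back to FASTA (cleaned residues)
#' @param x An `fi_dataset`.
#' @param path Output file path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  res <- dataset_residues(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(res)) {
    writeLines(paste0(">", names(res)[[i]]), con)
    s <- res[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write a distance matrix in PHYLIP square format
#'
#' Serialises a symmetric zero-diagonal distance matrix in the plain-text
#' square layout consumed by PHYLIP's `neighbor` program: a header line with
#' the taxon count, then one row per taxon with the name padded (or
#' truncated) to `name_width` characters followed by the distances with six
#' decimal places.
#'
#' @param d An [distance_matrix()] result (`fi_dist`) or a plain symmetric
#'   numeric matrix with dimnames.
#' @param path Output file path.
#' @param name_width Name field width; PHYLIP's classic format uses 10.
#' @param relaxed If `TRUE`, names longer than `name_width` are written in
#'   full (space-free) instead of truncated; strict mode errors if
#'   truncation makes two names collide.
#' @return `path`, invisibly.
#' @export
write_phylip_distance <- function(d, path, name_width = 10L, relaxed = FALSE) {
  m <- as.matrix(d)
  labels <- rownames(m)
  check_distance_matrix(m, labels)
  out_names <- gsub("[[:space:]]", "_", labels)
  if (!relaxed) {
    out_names <- substr(out_names, 1L, name_width)
    if (anyDuplicated(out_names)) {
      stop("taxon names collide after truncation to ", name_width,
           " characters; use relaxed = TRUE or rename: ",
           paste(unique(out_names[duplicated(out_names)]), collapse = ", "))
    }
  }
  pad <- formatC(out_names, width = name_width, flag = "-")
  rows <- vapply(seq_along(labels), function(i) {
    paste0(pad[[i]], " ", paste(sprintf("%.6f", m[i, ]), collapse = " "))
  }, character(1))
  writeLines(c(as.character(nrow(m)), rows), path)
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#'
#' Inverse of [write_phylip_distance()] within the format's six-decimal
#' precision. The body must be square and symmetric (tolerance `1e-6`).
#'
#' @param path Path to a PHYLIP square distance file.
#' @return A symmetric numeric matrix with taxon names as dimnames.
#' @export
read_phylip_distance <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty PHYLIP distance file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[[1]])))
  if (is.na(n) || n < 2L) stop("invalid taxon count header: ", lines[[1]])
  body <- lines[-1L]
  if (length(body) != n) {
    stop("header declares ", n, " taxa but file has ", length(body), " rows")
  }
  parts <- strsplit(trimws(body), "[[:space:]]+")
  labels <- vapply(parts, `[[`, character(1), 1L)
  vals <- lapply(parts, function(p) suppressWarnings(as.numeric(p[-1L])))
  if (any(vapply(vals, length, integer(1)) != n) || anyNA(unlist(vals))) {
    stop("non-square or non-numeric matrix body (expected ", n,
         " distances per row)")
  }
  m <- do.call(rbind, vals)
  dimnames(m) <- list(labels, labels)
  if (max(abs(m - t(m))) > 1e-6) stop("matrix body is not symmetric (tolerance 1e-6)")
  if (max(abs(diag(m))) > 1e-6) stop("matrix diagonal is not zero (tolerance 1e-6)")
  m
}

check_distance_matrix <- function(m, labels = rownames(m)) {
  if (is.null(labels)) stop("distance matrix needs taxon names as dimnames")
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (nrow(m) < 2L) stop("distance matrix needs at least 2 taxa")
  if (max(abs(m - t(m))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(diag(m) != 0)) stop("distance matrix diagonal must be zero")
  invisible(m)
}
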