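#' Read one locus alignment from FASTA
#'
#' @param path FASTA file with at least one record; all sequences must share
#'   one length (it is an alignment), labels must be unique.
#' @param name Locus identifier; defaults to the file name without extension.
#' @return An `alignment` object: list with `name`, `sequences` (named
#'   character vector, uppercase IUPAC + gap), `length` (bp).
#' @export
read_fasta_alignment <- function(path, name = NULL) {
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("no FASTA records in ", path)
  seqs <- toupper(vapply(as.character(dna), paste, "", collapse = ""))
  if (anyDuplicated(names(seqs)))
    stop("duplicate taxon labels in ", path)
  len <- unique(nchar(seqs))
  if (length(len) != 1L)
    stop("unequal sequence lengths in ", path,
         " (", paste(len, collapse = ", "), "); not an alignment")
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  structure(list(name = name, sequences = seqs, length = len),
            class = "alignment")
}

#' Construct an alignment in memory
#'
#' @param name Locus identifier.
#' @param sequences Named character vector of equal-length sequences.
#' @return An `alignment`.
#' @export
alignment <- function(name, sequences) {
  len <- unique(nchar(sequences))
  if (length(len) != 1L) stop("sequences must share one length")
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must be uniquely named")
  structure(list(name = name, sequences = toupper(sequences), length = len),
            class = "alignment")
}

#' Concatenate locus alignments into a partitioned supermatrix
#'
#' Partitions appear in input order with 1-based inclusive column
#' coordinates (the RAxML partition-file convention); taxa absent from a
#' locus are padded with `"-"` when `fill_missing` is `TRUE`, otherwise a
#' mismatching taxon set is an error.
#'
#' @param alignments List of `alignment` objects.
#' @param fill_missing Pad missing taxa with gaps?
#' @return A `supermatrix`: list with `sequences` (named character vector),
#'   `partitions` (data frame `name`, `start`, `end`), `total_length`.
#' @export
concatenate_alignments <- function(alignments, fill_missing = TRUE) {
  if (length(alignments) < 1L) stop("need at least one alignment")
  if (inherits(alignments, "alignment")) alignments <- list(alignments)
  taxa <- unique(unlist(lapply(alignments, function(a) names(a$sequences))))
  if (!fill_missing) {
    same <- vapply(alignments, function(a)
      setequal(names(a$sequences), taxa), TRUE)
    if (!all(same))
      stop("taxon sets differ between loci and fill_missing is FALSE")
  }
  lens <- vapply(alignments, `[[`, 0, "length")
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  nms <- vapply(seq_along(alignments), function(i) {
    nm <- alignments[[i]]$name
    if (is.null(nm) || !nzchar(trimws(nm))) sprintf("part%d", i) else nm
  }, "")
  blocks <- lapply(alignments, function(a) {
    s <- a$sequences[taxa]
    s[is.na(s)] <- strrep("-", a$length)
    s
  })
  seqs <- stats::setNames(do.call(paste0, blocks), taxa)
  structure(list(sequences = seqs,
                 partitions = data.frame(name = nms, start = starts,
                                         end = ends),
                 total_length = sum(lens)),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("Supermatrix:", length(x$sequences), "taxa,",
      nrow(x$partitions), "partitions,", x$total_length, "bp\n")
  invisible(x)
}

#' Write / read a RAxML-style partition file
#'
#' One line per partition: `DNA, <name> = <start>-<end>` with 1-based
#' inclusive coordinates; `read_partition_file` round-trips the table.
#'
#' @param sm A `supermatrix`.
#' @param path File path.
#' @export
write_partition_file <- function(sm, path) {
  pt <- sm$partitions
  writeLines(sprintf("DNA, %s = %d-%d", pt$name, pt$start, pt$end), path)
  invisible(path)
}

#' @rdname write_partition_file
#' @return `read_partition_file`: data frame `name`, `start`, `end`.
#' @export
read_partition_file <- function(path) {
  lines <- grep("^\\s*DNA\\s*,", readLines(path), value = TRUE)
  m <- regmatches(lines,
                  regexec("^\\s*DNA\\s*,\\s*(\\S+)\\s*=\\s*(\\d+)\\s*-\\s*(\\d+)", lines))
  bad <- lengths(m) != 4L
  if (any(bad)) stop("malformed partition line(s): ",
                     paste(lines[bad], collapse = "; "))
  data.frame(name = vapply(m, `[`, "", 2L),
             start = as.integer(vapply(m, `[`, "", 3L)),
             end = as.integer(vapply(m, `[`, "", 4L)))
}

#' Write a supermatrix as FASTA (+ partition file)
#'
#' @param sm A `supermatrix`.
#' @param prefix Output path prefix; writes `<prefix>.fasta` and
#'   `<prefix>.partitions`.
#' @return Invisibly, the two paths.
#' @export
write_supermatrix <- function(sm, prefix) {
  fa <- paste0(prefix, ".fasta")
  con <- file(fa, "w")
  for (i in seq_along(sm$sequences))
    writeLines(c(paste0(">", names(sm$sequences)[i]), sm$sequences[i]), con)
  close(con)
  pf <- paste0(prefix, ".partitions")
  write_partition_file(sm, pf)
  invisible(c(fa, pf))
}
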