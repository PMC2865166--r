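# Sequence, alignment and tree input/output plus the core containers.
# FASTA goes through Biostrings, Newick through ape; the alignment classes
# are thin S3 wrappers over named character vectors so they stay pipeable
# into tibbles.

#' Read a FASTA file
#'
#' @param path path to a FASTA file of nucleotide or amino-acid sequences.
#' @return A tibble with columns `id`, `description` and `residues`, one
#'   row per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) stop("not parseable as FASTA: ", path,
                                         " (", conditionMessage(e), ")"))
  if (length(x) == 0) stop("empty FASTA file: ", path)
  hdr <- names(x)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "))
  }
  res <- toupper(as.character(x))
  bad <- grepl("[^A-Z*.-]", res)
  if (any(bad))
    stop("non-alphabet characters in record(s): ",
         paste(id[bad], collapse = ", "))
  if (any(nchar(res) == 0))
    stop("empty sequence in record(s): ",
         paste(id[nchar(res) == 0], collapse = ", "))
  tibble(id = id, description = desc, residues = unname(res))
}

#' Write sequences to FASTA
#'
#' @param x a tibble as returned by [read_fasta()], an alignment object,
#'   or a named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  if (is.data.frame(x)) {
    ids <- x$id
    desc <- if ("description" %in% names(x)) x$description else ""
    seqs <- x$residues
    hdr <- ifelse(nzchar(desc), paste(ids, desc), ids)
  } else {
    seqs <- unclass(x)
    hdr <- names(seqs)
  }
  bs <- Biostrings::BStringSet(setNames(as.character(seqs), hdr))
  Biostrings::writeXStringSet(bs, path, width = width)
  invisible(path)
}

#' In-frame codon alignment
#'
#' Validates and wraps an aligned set of in-frame coding sequences. Rows
#' must share one length that is a multiple of 3, gaps may occur only as
#' whole `---` triplets, and no ungapped row may contain an internal stop
#' codon under the universal code.
#'
#' @param x named character vector of aligned sequences, or a tibble with
#'   `id` and `residues` columns.
#' @param reference optional id of the reference taxon used for
#'   reference-coordinate mapping.
#' @return An object of class `codon_alignment`.
#' @export
codon_alignment <- function(x, reference = NULL) {
  if (is.data.frame(x)) x <- setNames(toupper(x$residues), x$id)
  x <- toupper(x)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("sequences must be named")
  if (anyDuplicated(names(x)))
    stop("duplicate taxon ids: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  L <- unique(nchar(x))
  if (length(L) != 1) stop("aligned rows must all have the same length")
  if (L %% 3 != 0) stop("alignment length must be a multiple of 3, got ", L)
  if (L == 0) stop("empty alignment forbidden")
  for (tx in names(x)) {
    cods <- split_codons(x[[tx]])
    has_gap <- grepl("-", cods, fixed = TRUE)
    if (any(has_gap & cods != "---"))
      stop("gaps must form whole codon triplets; offending taxon: ", tx)
    aa <- codon_to_aa(cods[!has_gap])
    aa[is.na(aa)] <- "X"   # ambiguity codes
    stops <- which(aa == "*")
    # a stop is terminal only if it is the last non-gap codon of the row
    if (length(stops) > 0) {
      lastng <- max(which(!has_gap))
      codpos <- which(!has_gap)[stops]
      internal <- codpos[codpos != lastng]
      if (length(internal) > 0)
        stop("internal stop codon in taxon ", tx,
             " at codon ", internal[1])
    }
  }
  structure(x, class = "codon_alignment", reference = reference)
}

#' Amino-acid alignment container
#'
#' @param x named character vector of equal-length amino-acid rows, or a
#'   tibble with `id` and `residues`.
#' @param reference optional reference taxon id.
#' @return An object of class `aa_alignment`.
#' @export
aa_alignment <- function(x, reference = NULL) {
  if (is.data.frame(x)) x <- setNames(toupper(x$residues), x$id)
  x <- toupper(x)
  if (is.null(names(x))) stop("sequences must be named")
  if (anyDuplicated(names(x))) stop("duplicate taxon ids")
  if (length(unique(nchar(x))) != 1)
    stop("aligned rows must all have the same length")
  structure(x, class = "aa_alignment", reference = reference)
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon alignment:", length(x), "taxa x",
      nchar(unclass(x)[[1]]) / 3, "codons\n")
  invisible(x)
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("amino-acid alignment:", length(x), "taxa x",
      nchar(unclass(x)[[1]]), "residues\n")
  invisible(x)
}

#' @export
as_tibble.codon_alignment <- function(x, ...) {
  tibble(id = names(x), residues = unname(unclass(x)))
}

#' @export
as_tibble.aa_alignment <- function(x, ...) {
  tibble(id = names(x), residues = unname(unclass(x)))
}

aln_length_codons <- function(aln) nchar(unclass(aln)[[1]]) / 3

#' Translate a codon alignment
#'
#' Translates every row under the universal genetic code. Gap triplets
#' become `-`; a terminal stop codon (shared final column in which every
#' ungapped row carries a stop) is dropped from all rows; ambiguous codons
#' (containing N etc.) become `X`.
#'
#' @param aln a [codon_alignment].
#' @return An [aa_alignment] with the same taxa and the reference carried
#'   over.
#' @export
translate_alignment <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  rows <- unclass(aln)
  codrows <- lapply(rows, split_codons)
  ncod <- length(codrows[[1]])
  aas <- lapply(names(codrows), function(tx) {
    cods <- codrows[[tx]]
    aa <- character(length(cods))
    gap <- cods == "---"
    aa[gap] <- "-"
    tr <- codon_to_aa(cods[!gap])
    tr[is.na(tr)] <- "X"
    aa[!gap] <- tr
    stops <- which(aa == "*")
    internal <- stops[stops < max(which(!gap))]
    if (length(internal) > 0)
      stop("internal stop codon in taxon ", tx, " at codon ", internal[1])
    aa
  })
  names(aas) <- names(codrows)
  # drop the terminal stop column if any row ends in a stop
  last <- vapply(aas, function(a) a[ncod], "")
  if (any(last == "*")) {
    aas <- lapply(aas, function(a) a[-ncod])
  }
  out <- vapply(aas, paste, "", collapse = "")
  aa_alignment(out, reference = attr(aln, "reference"))
}

# ---- region masks -----------------------------------------------------

#' Region mask
#'
#' A set of 1-based inclusive intervals to remove from an alignment,
#' either in alignment columns or in ungapped reference-sequence
#' coordinates.
#'
#' @param start,end integer vectors of interval bounds (inclusive).
#' @param space `"alignment"` or `"reference"`.
#' @return A tibble of class `region_mask` with columns `start`, `end`,
#'   `space`.
#' @export
region_mask <- function(start, end, space = c("alignment", "reference")) {
  space <- match.arg(space)
  if (length(start) != length(end)) stop("start/end length mismatch")
  if (any(start > end)) stop("interval start must be <= end")
  if (any(start < 1)) stop("intervals are 1-based; start must be >= 1")
  m <- tibble(start = as.integer(start), end = as.integer(end),
              space = space)
  m <- dplyr::arrange(m, .data$start)
  if (nrow(m) > 1 && any(m$start[-1] <= m$end[-nrow(m)]))
    stop("intervals overlap after sorting")
  class(m) <- c("region_mask", class(m))
  m
}

#' Read a region mask from TSV
#'
#' Expects columns `space`, `start`, `end`.
#'
#' @param path TSV path.
#' @return A [region_mask()].
#' @export
read_region_mask <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("space", "start", "end") %in% names(d)))
    stop("mask TSV needs columns: space, start, end")
  sp <- unique(d$space)
  if (length(sp) != 1) stop("mask TSV must use a single coordinate space")
  region_mask(d$start, d$end, space = sp)
}

# map reference residue positions (ungapped index in the reference row) to
# alignment column indices; unit = residues for aa, codons for codon alns
ref_to_columns <- function(units, reference_row) {
  ungapped <- which(units != "-" & units != "---")
  setNames(ungapped, seq_along(ungapped))
}

#' Remove masked regions from an alignment
#'
#' Columns covered by the mask are removed. Reference-space intervals are
#' first mapped to alignment columns via the reference row's ungapped
#' positions (a reference coordinate is the residue's ungapped index in
#' the reference row). For codon alignments interval units are codons.
#'
#' @param aln a [codon_alignment] or [aa_alignment].
#' @param mask a [region_mask()]. An empty mask returns the alignment
#'   unchanged.
#' @return The same class of alignment with masked columns removed.
#' @export
mask_regions <- function(aln, mask) {
  is_codon <- inherits(aln, "codon_alignment")
  if (!is_codon && !inherits(aln, "aa_alignment"))
    stop("aln must be a codon_alignment or aa_alignment")
  if (nrow(mask) == 0) return(aln)
  rows <- unclass(aln)
  unitize <- function(s) if (is_codon) split_codons(s) else strsplit(s, "")[[1]]
  units <- lapply(rows, unitize)
  L <- length(units[[1]])
  space <- mask$space[1]
  if (space == "reference") {
    refid <- attr(aln, "reference")
    if (is.null(refid))
      stop("reference-space mask requires a reference taxon on the alignment")
    if (!refid %in% names(rows)) stop("reference taxon not in alignment: ", refid)
    refmap <- ref_to_columns(units[[refid]], rows[[refid]])
    maxref <- length(refmap)
    if (any(mask$end > maxref))
      stop("mask interval exceeds reference length (", maxref, ")")
    cols <- unlist(lapply(seq_len(nrow(mask)), function(i)
      unname(refmap[as.character(mask$start[i]:mask$end[i])])))
  } else {
    if (any(mask$end > L))
      stop("mask interval exceeds alignment length (", L, ")")
    cols <- unlist(lapply(seq_len(nrow(mask)), function(i)
      mask$start[i]:mask$end[i]))
  }
  cols <- sort(unique(cols))
  if (length(cols) >= L) stop("mask covers all columns; empty alignment forbidden")
  keep <- setdiff(seq_len(L), cols)
  out <- vapply(units, function(u) paste(u[keep], collapse = ""), "")
  if (is_codon) codon_alignment(out, reference = attr(aln, "reference"))
  else aa_alignment(out, reference = attr(aln, "reference"))
}

# ---- trees ------------------------------------------------------------

#' Read a Newick tree
#'
#' @param path path to a Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in ", path)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf names: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (!is.null(tr$edge.length) && any(!is.finite(tr$edge.length) | tr$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  tr
}

#' Write a Newick tree
#'
#' @param tree an [ape::phylo] tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
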