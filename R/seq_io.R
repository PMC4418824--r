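# FASTA and trait-table I/O, and coding-sequence translation.

#' Read a FASTA file into an alignment
#'
#' Identifiers are taken verbatim up to the first whitespace in the header.
#' Input is case-insensitive and upper-cased on ingest.  Nucleotide ambiguity
#' codes other than `N` are rejected in strict mode (the default) or masked
#' to `N` with `ambiguity = "mask"`, because the distance formulas downstream
#' assume unambiguous base counts.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"dna"` or `"aa"`.
#' @param aligned If `TRUE` (default) require equal record lengths.
#' @param ambiguity `"error"` (strict) or `"mask"` (replace IUPAC ambiguity
#'   codes other than `N` with `N`; for amino acids, `B/Z/J/U/O` with `X`).
#' @return A [alignment()] object with records in file order.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path, alphabet = c("dna", "aa"), aligned = TRUE,
                       ambiguity = c("error", "mask")) {
  alphabet <- match.arg(alphabet)
  ambiguity <- match.arg(ambiguity)
  if (!file.exists(path)) stop("no such file: ", path)
  recs <- seqinr::read.fasta(file = path, seqtype = "AA", as.string = TRUE,
                             whole.header = FALSE, set.attributes = FALSE)
  if (length(recs) == 0L) stop("no FASTA records in ", path)
  seqs <- toupper(vapply(recs, `[[`, character(1), 1L))
  ids <- names(recs)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(seqs) <- ids
  if (aligned && length(unique(nchar(seqs))) != 1L) {
    stop("ragged FASTA: record lengths ",
         paste(unique(nchar(seqs)), collapse = ", "),
         " (aligned input expected)")
  }
  if (ambiguity == "mask") {
    if (alphabet == "dna") {
      seqs <- vapply(seqs, function(s)
        chartr(paste(.DNA_AMBIG, collapse = ""),
               strrep("N", length(.DNA_AMBIG)), s), character(1))
    } else {
      seqs <- vapply(seqs, function(s) chartr("BZJUO", "XXXXX", s), character(1))
    }
  }
  if (!aligned) {
    # validate each record separately, keep as plain named vector
    out <- lapply(seq_along(seqs), function(i)
      alignment(seqs[i], alphabet = alphabet))
    res <- vapply(out, function(a) unclass(a)[[1]], character(1))
    names(res) <- ids
    return(structure(res, class = "seq_alignment", alphabet = alphabet))
  }
  alignment(seqs, alphabet = alphabet)
}

#' Write an alignment to FASTA
#'
#' @param aln A [alignment()] object (or named character vector).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path, width = 60L) {
  seqinr::write.fasta(sequences = as.list(unclass(aln)), names = names(aln),
                      file.out = path, nbchar = width, as.string = TRUE)
  invisible(path)
}

#' Translate a coding nucleotide sequence
#'
#' Standard genetic code.  The input length must be a multiple of three;
#' internal stop codons are an error unless `allow_internal_stop = TRUE`.
#' Codons containing gaps or `N` translate to `X`.  A terminal stop codon is
#' retained as `*` so callers can strip or check it explicitly.
#'
#' @param dna A single coding nucleotide sequence (character scalar).
#' @param allow_internal_stop Permit internal `*` codons.
#' @return The amino-acid string of length `nchar(dna)/3`.
#' @examples
#' translate_cds("TGTTATATTCAGAATTGTCCTCTTGGT")  # "CYIQNCPLG"
#' @export
translate_cds <- function(dna, allow_internal_stop = FALSE) {
  stopifnot(is.character(dna), length(dna) == 1L)
  dna <- toupper(dna)
  n <- nchar(dna)
  if (n == 0L || n %% 3L != 0L) {
    stop("coding sequence length ", n, " is not a multiple of 3")
  }
  codons <- substring(dna, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  aa <- vapply(codons, function(cd) {
    if (grepl("[^ACGT]", cd)) return("X")
    seqinr::translate(strsplit(cd, "", fixed = TRUE)[[1]])
  }, character(1), USE.NAMES = FALSE)
  internal_stop <- which(aa == "*")
  internal_stop <- internal_stop[internal_stop < length(aa)]
  if (length(internal_stop) && !allow_internal_stop) {
    stop("internal stop codon at codon position ",
         paste(internal_stop, collapse = ", "))
  }
  paste(aa, collapse = "")
}

#' Translate every sequence of a nucleotide alignment
#'
#' @inheritParams translate_cds
#' @param aln A DNA [alignment()].
#' @param drop_terminal_stop Remove a trailing `*` from every translation.
#' @return An amino-acid `seq_alignment`.
#' @export
translate_alignment <- function(aln, allow_internal_stop = FALSE,
                                drop_terminal_stop = TRUE) {
  stopifnot(attr(aln, "alphabet") == "dna")
  prot <- vapply(unclass(aln), translate_cds, character(1),
                 allow_internal_stop = allow_internal_stop)
  if (drop_terminal_stop) prot <- sub("\\*$", "", prot)
  names(prot) <- names(aln)
  alignment(prot, alphabet = "aa")
}

#' Read a tip trait table from CSV
#'
#' Expects a header `taxon,state` (any names; the first two columns are
#' used).  Duplicate taxa and empty states are errors.
#'
#' @param path CSV path.
#' @param valid_states Optional set of allowed states; inferred when `NULL`.
#' @return A [trait_assignment()].
#' @export
read_trait_table <- function(path, valid_states = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("trait table needs at least two columns (taxon, state)")
  states <- as.character(df[[2L]])
  names(states) <- as.character(df[[1L]])
  trait_assignment(states, valid_states = valid_states)
}

#' Write a trait assignment to CSV
#'
#' @param traits A [trait_assignment()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(traits, path) {
  write.csv(data.frame(taxon = names(traits), state = unclass(traits)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Rename alignment taxa or trait tips with an explicit map
#'
#' Species-name spellings often differ between sequence headers and tree tip
#' labels; rather than guessing, joins are made explicit with a rename map.
#'
#' @param x A `seq_alignment` or `trait_assignment`.
#' @param map Named character vector `old name -> new name`.  Names absent
#'   from the map are left unchanged.
#' @return `x` with identifiers renamed.
#' @export
rename_taxa <- function(x, map) {
  old <- names(x)
  hit <- old %in% names(map)
  old[hit] <- unname(map[old[hit]])
  if (anyDuplicated(old)) stop("rename map produces duplicate identifiers")
  names(x) <- old
  x
}
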