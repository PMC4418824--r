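# Core containers: multiple sequence alignments and tip trait assignments.

.DNA_CHARS <- c("A", "C", "G", "T", "-", "N")
.AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.AA_CHARS <- c(.AA_LETTERS, "-", "X")
# IUPAC nucleotide ambiguity codes other than N
.DNA_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Construct a sequence alignment
#'
#' An alignment is a named character vector of equal-length sequences over a
#' declared alphabet (`"dna"`: `A C G T - N`; `"aa"`: the 20 standard amino
#' acids plus `-` and `X`).  Taxa must be unique and non-empty.
#'
#' @param sequences Named character vector, one sequence per taxon.
#' @param alphabet `"dna"` or `"aa"`.
#' @return An object of class `seq_alignment`.
#' @examples
#' aln <- alignment(c(human = "ACGT", chimp = "ACGA"))
#' aln
#' @export
alignment <- function(sequences, alphabet = c("dna", "aa")) {
  alphabet <- match.arg(alphabet)
  if (length(sequences) == 0L) stop("alignment must contain at least one sequence")
  taxa <- names(sequences)
  if (is.null(taxa) || any(!nzchar(taxa))) {
    stop("all sequences must be named with non-empty taxon identifiers")
  }
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon identifiers: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "))
  }
  allowed <- if (alphabet == "dna") .DNA_CHARS else .AA_CHARS
  for (i in seq_along(sequences)) {
    ch <- unique(strsplit(sequences[[i]], "", fixed = TRUE)[[1]])
    bad <- setdiff(ch, allowed)
    if (length(bad)) {
      stop("illegal character(s) ", paste(bad, collapse = ", "),
           " in sequence for taxon '", taxa[i], "' (alphabet ", alphabet, ")")
    }
  }
  structure(sequences, class = "seq_alignment", alphabet = alphabet)
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("<seq_alignment> %d taxa x %d sites (%s)\n",
              length(x), nchar(x[[1]]), attr(x, "alphabet")))
  shown <- head(seq_along(x), 6L)
  for (i in shown) {
    s <- x[[i]]
    if (nchar(s) > 48) s <- paste0(substr(s, 1, 48), "...")
    cat(sprintf("  %-20s %s\n", names(x)[i], s))
  }
  if (length(x) > length(shown)) cat("  ...\n")
  invisible(x)
}

aln_taxa <- function(aln) names(aln)
aln_nsites <- function(aln) nchar(aln[[1]])

# alignment -> character matrix (taxa x sites)
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unclass(aln), "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

#' Construct a trait assignment
#'
#' Maps tip identifiers to categorical states (for example
#' monogamous / non-monogamous).  Every state must belong to the valid-state
#' set; by default that set is inferred from the data.
#'
#' @param states Named character vector: `tip identifier -> state`.
#' @param valid_states Optional character vector of allowed states.
#' @return An object of class `trait_assignment`.
#' @examples
#' trait_assignment(c(Callithrix = "M", Ateles = "N", Homo = "M"))
#' @export
trait_assignment <- function(states, valid_states = NULL) {
  tips <- names(states)
  if (is.null(tips) || any(!nzchar(tips))) stop("states must be named by tip identifier")
  if (anyDuplicated(tips)) {
    stop("duplicate tip identifiers: ",
         paste(unique(tips[duplicated(tips)]), collapse = ", "))
  }
  states <- as.character(states)
  names(states) <- tips
  if (any(is.na(states) | !nzchar(states))) stop("empty or missing state values")
  if (is.null(valid_states)) valid_states <- sort(unique(states))
  bad <- setdiff(unique(states), valid_states)
  if (length(bad)) stop("state(s) outside valid set: ", paste(bad, collapse = ", "))
  structure(states, class = "trait_assignment", valid_states = valid_states)
}

#' @export
print.trait_assignment <- function(x, ...) {
  tab <- table(unclass(x))
  cat(sprintf("<trait_assignment> %d tips; states: %s\n", length(x),
              paste(sprintf("%s (%d)", names(tab), tab), collapse = ", ")))
  invisible(x)
}
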