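# Pairwise evolutionary distances from nucleotide alignments.
#
# Corrections implemented: p-distance, JC69, K2P, Tamura 3-parameter (T92),
# each with an optional gamma rate-heterogeneity generalisation
# -ln(w) -> alpha * (w^(-1/alpha) - 1).  Gap/ambiguity handling is pairwise
# deletion by default (complete deletion available).  Saturated pairs raise
# errors rather than emitting non-finite values, because downstream matrix
# correlation requires finite entries.

#' Comparable sites, transitions and transversions for a sequence pair
#'
#' Positions holding a gap or `N` in either sequence are excluded (pairwise
#' deletion).  Transitions are `A<->G` and `C<->T`; every other difference is
#' a transversion.
#'
#' @param seq_a,seq_b Equal-length nucleotide strings.
#' @return A list with `comparable`, `transitions`, `transversions`, and the
#'   GC fractions `gc_a`, `gc_b` over comparable sites (used by the T92
#'   correction).
#' @examples
#' site_counts("ACGT", "GCTA")  # 4 comparable, 1 transition, 2 transversions
#' @export
site_counts <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) stop("sequences differ in length")
  .site_counts_chars(strsplit(toupper(seq_a), "", fixed = TRUE)[[1]],
                     strsplit(toupper(seq_b), "", fixed = TRUE)[[1]])
}

# core of site_counts on pre-split character vectors
.site_counts_chars <- function(a, b) {
  keep <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n == 0L) stop("zero comparable sites for this pair")
  diff <- a != b
  ts <- sum(diff & ((a == "A" & b == "G") | (a == "G" & b == "A") |
                    (a == "C" & b == "T") | (a == "T" & b == "C")))
  tv <- sum(diff) - ts
  list(comparable = n, transitions = ts, transversions = tv,
       gc_a = mean(a %in% c("G", "C")), gc_b = mean(b %in% c("G", "C")))
}

#' Uncorrected proportion of differing sites
#'
#' @inheritParams site_counts
#' @return The p-distance (differences / comparable sites), in `[0, 1]`.
#' @export
p_distance <- function(seq_a, seq_b) {
  sc <- site_counts(seq_a, seq_b)
  (sc$transitions + sc$transversions) / sc$comparable
}

# -ln(w) or its gamma generalisation alpha * (w^(-1/alpha) - 1)
.nlog <- function(w, alpha = NULL) {
  if (is.null(alpha)) -log(w) else alpha * (w^(-1 / alpha) - 1)
}

#' Jukes-Cantor corrected distance
#'
#' `-(3/4) ln(1 - 4p/3)`, or its gamma generalisation
#' `(3/4) alpha ((1 - 4p/3)^(-1/alpha) - 1)` when `alpha` is given.
#'
#' @param p Proportion of differing sites, `0 <= p < 0.75`.
#' @param alpha Optional gamma shape parameter (`> 0`).
#' @return Distance in substitutions/site.
#' @export
jc69 <- function(p, alpha = NULL) {
  if (any(p < 0)) stop("p must be non-negative")
  w <- 1 - 4 * p / 3
  if (any(w <= 0)) stop("saturated: p >= 0.75 has no JC69 correction")
  if (!is.null(alpha) && alpha <= 0) stop("alpha must be positive")
  0.75 * .nlog(w, alpha)
}

#' Kimura two-parameter corrected distance
#'
#' `-(1/2) ln(1-2P-Q) - (1/4) ln(1-2Q)` for transition proportion `P` and
#' transversion proportion `Q`; gamma generalisation replaces each `-ln`.
#'
#' @param P,Q Transition and transversion proportions.
#' @param alpha Optional gamma shape parameter.
#' @return Distance in substitutions/site.
#' @export
k2p <- function(P, Q, alpha = NULL) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (any(w1 <= 0) || any(w2 <= 0)) {
    stop("saturated: K2P log arguments must be positive (1-2P-Q = ",
         signif(w1, 4), ", 1-2Q = ", signif(w2, 4), ")")
  }
  if (!is.null(alpha) && alpha <= 0) stop("alpha must be positive")
  0.5 * .nlog(w1, alpha) + 0.25 * .nlog(w2, alpha)
}

#' Tamura three-parameter corrected distance
#'
#' `-h ln(1 - P/h - Q) - (1/2)(1-h) ln(1-2Q)` with `h = 2 theta (1 - theta)`
#' and `theta` the mean GC content of the pair over comparable sites.
#' Reduces to [k2p()] when `theta = 0.5`.
#'
#' @param P,Q Transition and transversion proportions.
#' @param gc_a,gc_b GC fractions of the two sequences over comparable sites.
#' @param alpha Optional gamma shape parameter.
#' @return Distance in substitutions/site.
#' @export
tamura92 <- function(P, Q, gc_a, gc_b, alpha = NULL) {
  theta <- (gc_a + gc_b) / 2
  h <- 2 * theta * (1 - theta)
  if (h <= 0) {
    stop("degenerate GC content (theta = ", theta,
         "): T92 correction undefined; use jc69/k2p instead")
  }
  w1 <- 1 - P / h - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) stop("saturated: T92 log arguments must be positive")
  if (!is.null(alpha) && alpha <= 0) stop("alpha must be positive")
  h * .nlog(w1, alpha) + 0.5 * (1 - h) * .nlog(w2, alpha)
}

.pair_distance <- function(chars_a, chars_b, model, alpha) {
  sc <- .site_counts_chars(chars_a, chars_b)
  P <- sc$transitions / sc$comparable
  Q <- sc$transversions / sc$comparable
  switch(model,
    p = P + Q,
    jc69 = jc69(P + Q, alpha),
    k2p = k2p(P, Q, alpha),
    t92 = tamura92(P, Q, sc$gc_a, sc$gc_b, alpha))
}

#' Pairwise evolutionary distance matrix
#'
#' Applies the chosen correction to every pair of an alignment.  Any pair
#' with zero comparable sites or a saturated correction aborts with an error
#' naming the offending pair; the matrix never contains non-finite values.
#'
#' @param aln A DNA [alignment()] with at least two taxa.
#' @param model One of `"p"`, `"jc69"`, `"k2p"`, `"t92"`.
#' @param gamma_alpha Optional gamma shape parameter applied to the
#'   correction (ignored for `model = "p"`).
#' @param gaps `"pairwise"` (default) excludes gap/`N` positions per pair;
#'   `"complete"` drops every column containing a gap/`N` in any sequence
#'   before computing distances.
#' @return A symmetric `evo_dist` matrix (zero diagonal) with attributes
#'   `model`, `gaps` and `gamma_alpha`.
#' @examples
#' aln <- alignment(c(a = "ACGTACGT", b = "ACGAACGA", c = "GCGTACTT"))
#' distance_matrix(aln, "jc69")
#' @export
distance_matrix <- function(aln, model = c("p", "jc69", "k2p", "t92"),
                            gamma_alpha = NULL,
                            gaps = c("pairwise", "complete")) {
  model <- match.arg(model)
  gaps <- match.arg(gaps)
  taxa <- names(aln)
  if (length(taxa) < 2L) stop("need at least two taxa")
  seqs <- unclass(aln)
  if (gaps == "complete") {
    m <- aln_matrix(aln)
    keep <- colSums(!(m == "A" | m == "C" | m == "G" | m == "T")) == 0L
    if (!any(keep)) stop("complete deletion removes every column")
    seqs <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  }
  n <- length(taxa)
  chars <- strsplit(toupper(unname(seqs)), "", fixed = TRUE)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dij <- tryCatch(
        .pair_distance(chars[[i]], chars[[j]], model, gamma_alpha),
        error = function(e) stop("pair (", taxa[i], ", ", taxa[j], "): ",
                                 conditionMessage(e), call. = FALSE))
      d[i, j] <- d[j, i] <- dij
    }
  }
  structure(d, class = c("evo_dist", "matrix"),
            model = model, gaps = gaps, gamma_alpha = gamma_alpha)
}

#' @export
print.evo_dist <- function(x, ...) {
  cat(sprintf("<evo_dist> %d taxa, model=%s, gaps=%s%s\n", nrow(x),
              attr(x, "model"), attr(x, "gaps"),
              if (is.null(attr(x, "gamma_alpha"))) ""
              else sprintf(", gamma_alpha=%g", attr(x, "gamma_alpha"))))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  invisible(x)
}

#' Write / read a distance matrix as square CSV
#'
#' Taxa appear as the header row and first column; the full symmetric matrix
#' is stored.  Model metadata is written as `# key: value` comment lines.
#'
#' @param dm An `evo_dist` matrix (or plain named square matrix).
#' @param path CSV path.
#' @return `path` invisibly (`write_distance_csv`); an `evo_dist`
#'   (`read_distance_csv`).
#' @export
write_distance_csv <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# model: %s", attr(dm, "model") %||% "unknown"), con)
  writeLines(sprintf("# gaps: %s", attr(dm, "gaps") %||% "unknown"), con)
  if (!is.null(attr(dm, "gamma_alpha"))) {
    writeLines(sprintf("# gamma_alpha: %g", attr(dm, "gamma_alpha")), con)
  }
  df <- data.frame(taxon = rownames(dm), unclass(dm), check.names = FALSE)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_distance_csv
#' @export
read_distance_csv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  df <- read.csv(text = paste(grep("^#", lines, invert = TRUE, value = TRUE),
                              collapse = "\n"), check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  get_meta <- function(key) {
    hit <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
    if (length(hit)) sub(paste0("^# ", key, ": "), "", hit[1L]) else NULL
  }
  structure(m, class = c("evo_dist", "matrix"),
            model = get_meta("model"), gaps = get_meta("gaps"),
            gamma_alpha = if (!is.null(get_meta("gamma_alpha")))
              as.numeric(get_meta("gamma_alpha")) else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
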