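# Radical/conservative substitution classification and per-domain
# substitution proportions along a receptor topology.
#
# A replacement is *radical* if it changes at least one of three amino-acid
# categories -- polarity, charge, side-chain volume class -- and
# *conservative* if it changes none.  The category table is data, not code:
# the default ships as inst/extdata/aa_categories.csv and can be replaced.

#' Amino-acid category table
#'
#' Polarity (`polar`/`nonpolar`), charge (`positive`/`negative`/`neutral`)
#' and an ordinal side-chain volume class for each of the 20 standard amino
#' acids.  The default table uses charge positive `{K,R,H}`, negative
#' `{D,E}`; polarity polar `{R,N,D,C,Q,E,H,K,S,T,Y}`; and five volume
#' classes cut from Zamyatnin side-chain volumes.
#'
#' @param path Optional CSV with columns `aa,polarity,charge,volume_class`
#'   covering all 20 amino acids; the shipped default is used when `NULL`.
#' @return A data frame of class `aa_category_table`, rownames = amino acid.
#' @export
aa_category_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aa_categories.csv",
                        package = "oxtkit", mustWork = TRUE)
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("aa", "polarity", "charge", "volume_class")
  if (!all(need %in% names(df))) {
    stop("category table must have columns ", paste(need, collapse = ", "))
  }
  missing <- setdiff(.AA_LETTERS, df$aa)
  if (length(missing)) {
    stop("category table missing amino acid(s): ", paste(missing, collapse = ", "))
  }
  stopifnot(all(df$polarity %in% c("polar", "nonpolar")),
            all(df$charge %in% c("positive", "negative", "neutral")))
  rownames(df) <- df$aa
  structure(df, class = c("aa_category_table", "data.frame"))
}

#' Classify an amino-acid substitution as radical or conservative
#'
#' Compares the polarity, charge and volume classes of the two residues; a
#' change in one or more categories is radical, no change in all three is
#' conservative.  The verdict is symmetric in its arguments.
#'
#' @param ref_aa,alt_aa Distinct standard amino acids (single letters).
#' @param table An [aa_category_table()].
#' @return A list: `verdict` (`"radical"` or `"conservative"`) and
#'   `changed` (character subset of `polarity`, `charge`, `volume`).
#' @examples
#' classify_substitution("L", "P")$verdict  # radical (volume class changes)
#' classify_substitution("I", "L")$verdict  # conservative
#' @export
classify_substitution <- function(ref_aa, alt_aa, table = aa_category_table()) {
  for (aa in c(ref_aa, alt_aa)) {
    if (!aa %in% rownames(table)) stop("nonstandard residue: ", aa)
  }
  if (ref_aa == alt_aa) stop("residues are identical; not a substitution")
  changed <- c(
    if (table[ref_aa, "polarity"] != table[alt_aa, "polarity"]) "polarity",
    if (table[ref_aa, "charge"] != table[alt_aa, "charge"]) "charge",
    if (table[ref_aa, "volume_class"] != table[alt_aa, "volume_class"]) "volume")
  list(verdict = if (length(changed)) "radical" else "conservative",
       changed = changed %||% character(0))
}

#' Substitutions of an aligned sequence relative to a reference
#'
#' One record per alignment column where both residues are standard amino
#' acids and differ.  Columns containing a gap or `X` in either sequence are
#' skipped and counted separately (attribute `n_indel_columns`).
#'
#' @param aligned_seq,aligned_ref Equal-length aligned amino-acid strings.
#' @param table An [aa_category_table()] used to classify each record.
#' @return A data frame of class `substitution_records` with columns
#'   `column` (1-based), `ref`, `alt`, `domain` (`NA` until
#'   [annotate_domains()]), `verdict`, `changed` (comma-joined categories).
#' @export
substitutions_vs_reference <- function(aligned_seq, aligned_ref,
                                       table = aa_category_table()) {
  if (nchar(aligned_seq) != nchar(aligned_ref)) {
    stop("aligned sequence and reference differ in length")
  }
  q <- strsplit(toupper(aligned_seq), "", fixed = TRUE)[[1]]
  r <- strsplit(toupper(aligned_ref), "", fixed = TRUE)[[1]]
  standard <- q %in% .AA_LETTERS & r %in% .AA_LETTERS
  n_indel <- sum(!standard)
  idx <- which(standard & q != r)
  recs <- data.frame(column = idx, ref = r[idx], alt = q[idx],
                     domain = rep(NA_character_, length(idx)),
                     verdict = character(length(idx)),
                     changed = character(length(idx)),
                     stringsAsFactors = FALSE)
  for (i in seq_along(idx)) {
    cl <- classify_substitution(recs$ref[i], recs$alt[i], table)
    recs$verdict[i] <- cl$verdict
    recs$changed[i] <- paste(cl$changed, collapse = ",")
  }
  structure(recs, class = c("substitution_records", "data.frame"),
            n_indel_columns = n_indel)
}

#' Read a domain annotation from CSV
#'
#' Columns `label,start,end` (1-based inclusive alignment columns).
#' Intervals must be sorted and non-overlapping.  A default approximate
#' human-receptor topology (`N-term`, `TM1..TM7`, `ICL1..ICL3`,
#' `ECL1..ECL3`, `C-term`) ships as
#' `inst/extdata/oxtr_domains_default.csv`.
#'
#' @param path CSV path, or `NULL` for the shipped default.
#' @return A data frame of class `domain_annotation`.
#' @export
read_domain_annotation <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "oxtr_domains_default.csv",
                        package = "oxtkit", mustWork = TRUE)
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "start", "end")
  if (!all(need %in% names(df))) {
    stop("domain annotation must have columns ", paste(need, collapse = ", "))
  }
  if (any(df$start > df$end)) stop("domain with start > end")
  df <- df[order(df$start), ]
  if (nrow(df) > 1L && any(df$start[-1L] <= df$end[-nrow(df)])) {
    stop("overlapping domain intervals")
  }
  rownames(df) <- NULL
  structure(df, class = c("domain_annotation", "data.frame"))
}

.find_domain <- function(columns, annotation) {
  vapply(columns, function(col) {
    hit <- which(annotation$start <= col & col <= annotation$end)
    if (!length(hit)) {
      stop("alignment column ", col, " falls outside every annotated domain")
    }
    annotation$label[hit[1L]]
  }, character(1))
}

#' Assign a domain label to each substitution record
#'
#' @param records A `substitution_records` data frame.
#' @param annotation A [read_domain_annotation()] table covering every
#'   record's column.
#' @return `records` with the `domain` column filled.
#' @export
annotate_domains <- function(records, annotation) {
  if (nrow(records)) records$domain <- .find_domain(records$column, annotation)
  records
}

#' Per-domain substitution proportions
#'
#' For each annotated domain, the number of distinct substituted columns
#' divided by the domain length (default) or by the total substitution
#' count (`denominator = "total_substitutions"`).
#'
#' @param records A `substitution_records` data frame (domains need not be
#'   pre-annotated).
#' @param annotation A [read_domain_annotation()] table.
#' @param denominator `"domain_length"` or `"total_substitutions"`.
#' @return A named numeric vector, one proportion per domain label.
#' @export
domain_proportions <- function(records, annotation,
                               denominator = c("domain_length",
                                               "total_substitutions")) {
  denominator <- match.arg(denominator)
  cols <- unique(records$column)
  doms <- if (length(cols)) .find_domain(cols, annotation) else character(0)
  counts <- table(factor(doms, levels = annotation$label))
  den <- if (denominator == "domain_length") {
    setNames(annotation$end - annotation$start + 1L, annotation$label)
  } else {
    setNames(rep(max(length(cols), 1L), nrow(annotation)), annotation$label)
  }
  as.numeric(counts) / as.numeric(den[names(counts)]) -> props
  setNames(props, names(counts))
}

#' Per-species, per-domain substitution proportions
#'
#' Convenience wrapper: compares every non-reference sequence of an aligned
#' amino-acid alignment to the reference taxon and tabulates per-domain
#' substitution proportions.
#'
#' @param aln An amino-acid [alignment()].
#' @param reference_taxon Name of the reference sequence in `aln`.
#' @param annotation A [read_domain_annotation()] table.
#' @param table An [aa_category_table()].
#' @return A matrix (species x domain) of proportions, with attribute
#'   `records` (named list of per-species `substitution_records`).
#' @export
substitution_proportions <- function(aln, reference_taxon,
                                     annotation = read_domain_annotation(),
                                     table = aa_category_table()) {
  if (!reference_taxon %in% names(aln)) {
    stop("reference taxon '", reference_taxon, "' not in alignment")
  }
  ref <- unclass(aln)[[reference_taxon]]
  others <- setdiff(names(aln), reference_taxon)
  recs <- lapply(others, function(tx) {
    r <- substitutions_vs_reference(unclass(aln)[[tx]], ref, table)
    annotate_domains(r, annotation)
  })
  names(recs) <- others
  props <- t(vapply(recs, domain_proportions, numeric(nrow(annotation)),
                    annotation = annotation))
  structure(props, records = recs)
}

#' Welch t-test on two groups of per-species proportions
#'
#' Independent-samples comparison of per-species substitution proportions
#' between two groups (for example species carrying different ligand
#' variants), using the unequal-variance Welch test.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return A list: `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
group_proportion_test <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 observations")
  }
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(t = 0, df = length(group_a) + length(group_b) - 2,
                  p_value = 1, mean_a = mean(group_a), mean_b = mean(group_b)))
    }
    stop("zero variance in both groups with unequal means; t undefined")
  }
  ht <- t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_a = mean(group_a), mean_b = mean(group_b))
}
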