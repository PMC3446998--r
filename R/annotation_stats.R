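# Per-protein annotation handling: BLAST tabular best hits, annotation
# TSVs, and the group-level summaries (conservation means + ANOVA/Duncan,
# pathway category fractions, subcellular-location cross-tabs).

#' Read BLAST tabular output and keep the best hit per query
#'
#' Expects the 12-column tabular dialect (qseqid, sseqid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore);
#' comment lines starting with `#` are ignored. For each query the single
#' hit with the maximal bit score is retained (ties broken by smaller
#' e-value, then subject id). Queries absent from the file simply have no
#' entry — "no hit" is represented by absence, and downstream summaries
#' exclude such proteins rather than zero-filling them.
#'
#' @param path File path, connection or character vector of lines.
#' @return Data frame with columns `protein_id`, `blast_bits`, `evalue`,
#'   `subject`; zero rows for an empty file.
#' @export
read_blast_tabular <- function(path) {
  raw <- if (is.character(path) && length(path) == 1L && file.exists(path)) {
    readLines(path)
  } else if (inherits(path, "connection")) {
    readLines(path)
  } else {
    as.character(path)
  }
  lineno <- seq_along(raw)
  keep <- !grepl("^#", raw) & nzchar(trimws(raw))
  raw <- raw[keep]
  lineno <- lineno[keep]
  if (length(raw) == 0L) {
    return(data.frame(protein_id = character(0), blast_bits = numeric(0),
                      evalue = numeric(0), subject = character(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 12L)
  if (length(bad)) {
    stop(sprintf("BLAST tabular format error at line %d: expected 12 columns, got %d",
                 lineno[bad[1L]], nf[bad[1L]]))
  }
  q <- vapply(fields, `[[`, "", 1L)
  s <- vapply(fields, `[[`, "", 2L)
  ev <- as.numeric(vapply(fields, `[[`, "", 11L))
  bits <- as.numeric(vapply(fields, `[[`, "", 12L))
  if (anyNA(ev) || anyNA(bits)) {
    stop("BLAST tabular format error: non-numeric evalue/bitscore field")
  }
  ord <- order(q, -bits, ev, s, method = "radix")
  first <- ord[!duplicated(q[ord])]
  data.frame(protein_id = q[first], blast_bits = bits[first],
             evalue = ev[first], subject = s[first],
             stringsAsFactors = FALSE)
}

#' Read a per-protein annotation TSV
#'
#' Format: `protein_id`, `blast_bits`, `evalue`, `length_aa`,
#' `pathway_labels` (semicolon-separated, may be empty), and 0/1 flags
#' `nucleus`, `cytoplasm`, `membrane`. Missing BLAST hits are encoded as
#' `NA` in `blast_bits`/`evalue`.
#'
#' @param path File path.
#' @return Data frame (`annotation_table`): one row per protein, location
#'   flags as logicals.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  needed <- c("protein_id", "blast_bits", "evalue", "length_aa",
              "pathway_labels", "nucleus", "cytoplasm", "membrane")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop("annotation table missing column(s): ", paste(miss, collapse = ", "))
  }
  df$pathway_labels[is.na(df$pathway_labels)] <- ""
  for (fl in c("nucleus", "cytoplasm", "membrane")) {
    df[[fl]] <- as.logical(as.integer(df[[fl]]))
  }
  validate_annotations(df)
}

validate_annotations <- function(df) {
  if (anyDuplicated(df$protein_id)) stop("duplicate protein_id in annotations")
  if (any(df$blast_bits < 0, na.rm = TRUE)) stop("blast_bits must be >= 0")
  if (any(df$length_aa < 1, na.rm = TRUE)) stop("length_aa must be >= 1")
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' Write an annotation table TSV
#'
#' @param ann Annotation data frame (see [read_annotations()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  out <- data.frame(
    protein_id = ann$protein_id,
    blast_bits = ann$blast_bits,
    evalue = ann$evalue,
    length_aa = ann$length_aa,
    pathway_labels = ann$pathway_labels,
    nucleus = as.integer(ann$nucleus),
    cytoplasm = as.integer(ann$cytoplasm),
    membrane = as.integer(ann$membrane),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

ann_rows <- function(ann, ids, context) {
  idx <- match(ids, ann$protein_id)
  missing <- ids[is.na(idx)]
  frac <- if (length(ids)) 1 - length(missing) / length(ids) else 1
  if (frac < 0.8) {
    stop(sprintf("%s: annotations available for only %.0f%% of members (missing: %s)",
                 context, 100 * frac,
                 paste(utils::head(missing, 10L), collapse = ", ")))
  }
  ann[idx[!is.na(idx)], , drop = FALSE]
}

#' Conservation and length summary for top/mid/bottom rank groups
#'
#' Joins a [extract_groups()] result to an annotation table and computes,
#' per group, mean BLAST bit score and mean protein length, together with
#' one-way ANOVA and Duncan letters across the three groups for each
#' variable. Proteins without a BLAST hit (`NA` bits) are excluded from
#' the whole group (both variables) with a reported count, so the
#' effective n can drop below k. Each group must retain annotations for at
#' least 80% of its members.
#'
#' @param groups A `rank_groups` object.
#' @param ann Annotation table.
#' @param alpha Significance level for the Duncan letters.
#' @return Object of class `group_summary`: `table` (data frame with
#'   `group`, `n`, `n_excluded`, `mean_bits`, `letter_bits`,
#'   `mean_length`, `letter_length`), `anova_bits`, `anova_length`,
#'   `duncan_bits`, `duncan_length`.
#' @export
group_conservation_summary <- function(groups, ann, alpha = 0.05) {
  stopifnot(inherits(groups, "rank_groups"))
  gl <- list(top = groups$top, mid = groups$mid, bottom = groups$bottom)
  rows <- mapply(function(ids, nm) ann_rows(ann, ids, paste0(nm, " group")),
                 gl, names(gl), SIMPLIFY = FALSE)
  n_excluded <- vapply(rows, function(r) sum(is.na(r$blast_bits)), integer(1))
  if (any(n_excluded > 0L)) {
    message(sprintf("excluding proteins without BLAST hits: %s",
                    paste(sprintf("%s=%d", names(rows), n_excluded),
                          collapse = ", ")))
  }
  rows <- lapply(rows, function(r) r[!is.na(r$blast_bits), , drop = FALSE])
  if (any(vapply(rows, nrow, integer(1)) == 0L)) {
    stop("a group is empty after excluding proteins without BLAST hits")
  }
  bits <- lapply(rows, `[[`, "blast_bits")
  lens <- lapply(rows, function(r) as.numeric(r$length_aa))
  av_b <- anova_oneway(bits)
  av_l <- anova_oneway(lens)
  du_b <- duncan_mrt(bits, alpha = alpha)
  du_l <- duncan_mrt(lens, alpha = alpha)
  tab <- data.frame(
    group = names(rows),
    n = vapply(rows, nrow, integer(1)),
    n_excluded = n_excluded,
    mean_bits = vapply(bits, mean, numeric(1)),
    letter_bits = du_b$letters[match(names(rows), du_b$group)],
    mean_length = vapply(lens, mean, numeric(1)),
    letter_length = du_l$letters[match(names(rows), du_l$group)],
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(
    list(table = tab, anova_bits = av_b, anova_length = av_l,
         duncan_bits = du_b, duncan_length = du_l, alpha = alpha,
         method = groups$method),
    class = "group_summary"
  )
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("group_summary (%s ranking):\n", x$method))
  print(x$table, row.names = FALSE)
  cat(sprintf("ANOVA bits:   F=%.4g p=%.4g\nANOVA length: F=%.4g p=%.4g\n",
              x$anova_bits$F, x$anova_bits$p,
              x$anova_length$F, x$anova_length$p))
  invisible(x)
}

#' Fraction of a protein group carrying a pathway label
#'
#' Reports the count of group members whose semicolon-separated
#' `pathway_labels` contain `label`, plus two percentage conventions: over
#' members with at least one pathway label ("of annotated") and over all
#' group members — both are in common use for such category tables.
#'
#' @param group Character vector of protein identifiers.
#' @param ann Annotation table.
#' @param label Pathway label to count (e.g. `"signalling"`, `"MAPK"`).
#' @return List with `count`, `percent_of_annotated`, `percent_of_all`,
#'   `n_annotated`, `n`.
#' @export
category_fraction <- function(group, ann, label) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  idx <- match(group, ann$protein_id)
  labs <- ann$pathway_labels[idx]
  labs[is.na(labs)] <- ""
  sets <- strsplit(labs, ";", fixed = TRUE)
  sets <- lapply(sets, function(s) trimws(s[nzchar(trimws(s))]))
  hit <- vapply(sets, function(s) label %in% s, logical(1))
  annotated <- lengths(sets) > 0L
  n <- length(group)
  n_ann <- sum(annotated)
  count <- sum(hit)
  list(count = count,
       percent_of_annotated = if (n_ann) 100 * count / n_ann else 0,
       percent_of_all = if (n) 100 * count / n else 0,
       n_annotated = n_ann, n = n)
}

#' Subcellular-location cross-tabulation of protein groups
#'
#' Per-group counts of nucleus, cytoplasm and membrane proteins, plus the
#' multi-location count "in both nucleus and another" (nucleus flag AND
#' any other flag). A protein may carry several flags, so rows need not
#' sum to the group size.
#'
#' @param groups Named list of protein-identifier vectors (e.g. forward
#'   top 50, forward bottom 50, ...).
#' @param ann Annotation table.
#' @return Data frame with columns `group`, `n`, `nucleus`, `cytoplasm`,
#'   `membrane`, `nucleus_plus`.
#' @export
location_crosstab <- function(groups, ann) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  one <- function(ids, nm) {
    idx <- match(ids, ann$protein_id)
    nuc <- ann$nucleus[idx] %in% TRUE
    cyt <- ann$cytoplasm[idx] %in% TRUE
    mem <- ann$membrane[idx] %in% TRUE
    data.frame(group = nm, n = length(ids),
               nucleus = sum(nuc), cytoplasm = sum(cyt),
               membrane = sum(mem),
               nucleus_plus = sum(nuc & (cyt | mem)),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, mapply(one, groups, names(groups), SIMPLIFY = FALSE))
  row.names(out) <- NULL
  out
}
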