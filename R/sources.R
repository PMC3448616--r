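# Natural-source annotation: join screening hits to the curated
# molecule -> source table and categorize each hit-source pair by the
# antidiabetic evidence for the source (reported directly, shared genus
# with a reported source, or neither).

.flag_levels <- c("reported", "genus_related", "none")

#' Read a molecule/source annotation table
#'
#' Tab-separated with header
#' `molecule_id  source_name  genus  antidiabetic_flag  references`.
#' The genus must equal the first token of the binomial source name
#' (case-insensitive) and flags must come from
#' `reported`/`genus_related`/`none`.
#'
#' @param path TSV file.
#' @return data.frame of source records.
#' @export
read_source_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("molecule_id", "source_name", "genus", "antidiabetic_flag",
            "references")
  if (!all(need %in% names(tab)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  first_tok <- vapply(strsplit(tab$source_name, "\\s+"), `[[`, "", 1L)
  if (any(tolower(first_tok) != tolower(tab$genus)))
    stop("genus column must equal the first token of source_name")
  if (!all(tab$antidiabetic_flag %in% .flag_levels))
    stop("antidiabetic_flag must be one of: ",
         paste(.flag_levels, collapse = ", "))
  tab[need]
}

#' Categorize screening hits by the evidence for their natural sources
#'
#' A hit-source pair is `antidiabetic_source` when the source's flag is
#' `reported`; `genus_related_source` when the source's flag marks it as
#' genus-related, or is `none` while some table record of the same genus
#' is flagged `reported`; otherwise `other_source`. Hits without any
#' record are listed in the `unannotated` attribute.
#'
#' @param hits character vector of hit molecule ids.
#' @param records annotation data.frame (see [read_source_table()]).
#' @param clusters optional named cluster membership vector to carry
#'   cluster indices into the report.
#' @return object of class `extract_report`: data.frame rows
#'   `(molecule_id, cluster_index, source_name, genus, category)` with
#'   a `summary` attribute of per-category counts.
#' @export
categorize_hits <- function(hits, records, clusters = NULL) {
  stopifnot(is.character(hits))
  reported_genera <- unique(tolower(records$genus[
    records$antidiabetic_flag == "reported"]))
  rows <- records[records$molecule_id %in% hits, , drop = FALSE]
  category <- character(nrow(rows))
  for (k in seq_len(nrow(rows))) {
    fl <- rows$antidiabetic_flag[k]
    category[k] <- if (fl == "reported") "antidiabetic_source"
    else if (fl == "genus_related" ||
             (fl == "none" && tolower(rows$genus[k]) %in% reported_genera))
      "genus_related_source"
    else "other_source"
  }
  out <- data.frame(
    molecule_id = rows$molecule_id,
    cluster_index = if (is.null(clusters)) rep(NA_integer_, nrow(rows)) else
      as.integer(clusters[rows$molecule_id]),
    source_name = rows$source_name,
    genus = rows$genus,
    category = category,
    row.names = NULL)
  out <- out[order(out$category, out$source_name, out$molecule_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  cats <- c("antidiabetic_source", "genus_related_source", "other_source")
  summary <- setNames(vapply(cats, function(cc) sum(out$category == cc), 0L),
                      cats)
  structure(out, summary = summary,
            unannotated = setdiff(hits, records$molecule_id),
            class = c("extract_report", "data.frame"))
}

#' Per-source distinct-hit counts
#'
#' @param report an `extract_report`.
#' @return data.frame `(source_name, n_hits)` sorted by count
#'   descending then source name.
#' @export
summarize_by_source <- function(report) {
  if (!nrow(report)) {
    return(data.frame(source_name = character(), n_hits = integer()))
  }
  agg <- tapply(report$molecule_id, report$source_name,
                function(x) length(unique(x)))
  out <- data.frame(source_name = names(agg), n_hits = as.integer(agg),
                    row.names = NULL)
  out[order(-out$n_hits, out$source_name), , drop = FALSE]
}

#' Write an extract report as TSV
#' @param report an `extract_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_extract_report <- function(report, path) {
  write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
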