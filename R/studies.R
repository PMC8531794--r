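#' @importFrom stats pchisq pnorm qnorm rnorm rmultinom lm coef setNames
#' @importFrom utils read.delim write.table
NULL

# Closed code vocabularies for study metadata. The cancer-type vocabulary is
# defined by the bundled cancer-group mapping so it can be extended by a
# sidecar file without touching code.
.ethnicities <- c("European", "East Asian", "West Asian", "African")
.control_sources <- c("PB", "HB")

.required_cols <- c("author", "year", "origin", "cancer_type", "ethnicity",
                    "control_source", "genotyping_method",
                    "case_tt", "case_tc", "case_cc",
                    "control_tt", "control_tc", "control_cc")
.count_cols <- c("case_tt", "case_tc", "case_cc",
                 "control_tt", "control_tc", "control_cc")

#' Cancer-type to cancer-group mapping
#'
#' Reads the mapping of cancer-type codes (e.g. \code{GC}, \code{BLCA}) to
#' analysis groups (\code{digestive}, \code{urinary}, \code{lung},
#' \code{breast}, \code{other}). Bladder and prostate cancers form the
#' urinary group; gastric, esophageal, colon and rectal cancers the
#' digestive group; Kaposi sarcoma is "other".
#'
#' @param path Optional path to a two-column tab-separated mapping file
#'   (\code{cancer_type}, \code{group}); defaults to the bundled mapping.
#' @return A data frame with columns \code{cancer_type} and \code{group}.
#' @export
cancer_group_map <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.pkg_cache$group_map)) {
      path <- system.file("extdata", "cancer_groups.tsv",
                          package = "snpmeta", mustWork = TRUE)
      .pkg_cache$group_map <- read.delim(path, stringsAsFactors = FALSE)
    }
    return(.pkg_cache$group_map)
  }
  map <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("cancer_type", "group") %in% names(map)))
  map
}

.pkg_cache <- new.env(parent = emptyenv())

#' Assemble a validated study set
#'
#' A study set is a data frame with one row per case-control study and the
#' fixed column schema used throughout the package: study metadata plus the
#' six genotype counts (\code{case_tt}, \code{case_tc}, \code{case_cc} and
#' the control counterparts). Validation enforces non-negative integer
#' counts, positive per-arm totals, closed metadata vocabularies, and
#' uniqueness of (author, year, cancer_type).
#'
#' @param df A data frame carrying at least the required columns.
#' @param label Optional label attached to the set.
#' @return A \code{study_set}: the validated data frame with an added
#'   \code{study_id} column and per-arm totals.
#' @export
study_set <- function(df, label = "study set") {
  miss <- setdiff(.required_cols, names(df))
  if (length(miss) > 0)
    stop("study table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0)
    stop("study set is empty: at least one study row is required",
         call. = FALSE)
  for (cl in .count_cols) {
    v <- df[[cl]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad) > 0)
      stop("column '", cl, "' has a negative or non-integer count at row ",
           bad[1], call. = FALSE)
    df[[cl]] <- as.integer(v)
  }
  df$year <- as.integer(df$year)
  df$n_case <- df$case_tt + df$case_tc + df$case_cc
  df$n_control <- df$control_tt + df$control_tc + df$control_cc
  if (any(df$n_case == 0) || any(df$n_control == 0))
    stop("every study must have at least one case and one control",
         call. = FALSE)
  vocab <- cancer_group_map()$cancer_type
  for (chk in list(c("cancer_type", paste(vocab, collapse = "|")),
                   c("ethnicity", paste(.ethnicities, collapse = "|")),
                   c("control_source", paste(.control_sources, collapse = "|")))) {
    allowed <- strsplit(chk[2], "|", fixed = TRUE)[[1]]
    bad <- which(!df[[chk[1]]] %in% allowed)
    if (length(bad) > 0)
      stop("unknown ", chk[1], " code '", df[[chk[1]]][bad[1]],
           "' at row ", bad[1], call. = FALSE)
  }
  full <- paste(df$author, df$year, df$origin, df$cancer_type)
  if (anyDuplicated(full))
    stop("duplicate study identity (author, year, origin, cancer_type): ",
         full[duplicated(full)][1], call. = FALSE)
  id <- paste(df$author, df$year, df$cancer_type)
  dup <- id %in% id[duplicated(id)]
  id[dup] <- paste(df$author, df$year, df$origin, df$cancer_type)[dup]
  df$study_id <- id
  structure(df, label = label, class = c("study_set", "data.frame"))
}

#' Read case-control genotype studies from a delimited text file
#'
#' @param path Path to a tab- or comma-separated UTF-8 text file with a
#'   header row. Column order is free; names are fixed (see
#'   \code{\link{study_set}}). Extra columns are carried along untouched.
#' @param sep Field separator; \code{NULL} (default) auto-detects tab vs
#'   comma from the header line.
#' @return A \code{\link{study_set}}.
#' @export
read_studies <- function(path, sep = NULL) {
  if (!file.exists(path))
    stop("study file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   check.names = TRUE, fileEncoding = "UTF-8")
  study_set(df, label = basename(path))
}

#' Write a study set back to delimited text
#'
#' Writes the same schema \code{\link{read_studies}} accepts, so a round
#' trip reproduces all field values.
#'
#' @param set A \code{study_set}.
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @export
write_studies <- function(set, path, sep = "\t") {
  keep <- setdiff(names(set), c("study_id", "n_case", "n_control"))
  write.table(as.data.frame(set)[, keep], path, sep = sep,
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' The bundled CXCR2 C1208T study table
#'
#' Eleven published cancer case-control studies of the CXCR2 C1208T
#' polymorphism (4,909 cases, 5,884 controls), with genotype counts for
#' both arms and, as reference metadata, the Hardy-Weinberg p-values
#' reported alongside the original counts (\code{hwe_case},
#' \code{hwe_control} columns; these are never used in computation).
#'
#' @param check Verify the bundled file against its shipped md5 checksum
#'   (default \code{TRUE}).
#' @return A \code{\link{study_set}} of 11 studies.
#' @export
cxcr2_studies <- function(check = TRUE) {
  path <- system.file("extdata", "cxcr2_c1208t_studies.tsv",
                      package = "snpmeta", mustWork = TRUE)
  if (check) {
    want <- readLines(paste0(path, ".md5"), n = 1L)
    got <- unname(tools::md5sum(path))
    if (!identical(got, want))
      stop("bundled study table failed its checksum: ", got, call. = FALSE)
  }
  read_studies(path)
}

#' Classify studies into cancer groups
#'
#' @param set A \code{study_set} (or any data frame with a
#'   \code{cancer_type} column).
#' @param map Mapping data frame from \code{\link{cancer_group_map}}.
#' @return Character vector of group codes, one per study.
#' @export
cancer_group <- function(set, map = cancer_group_map()) {
  g <- map$group[match(set$cancer_type, map$cancer_type)]
  if (anyNA(g))
    stop("no cancer-group mapping for type '",
         set$cancer_type[which(is.na(g))[1]], "'", call. = FALSE)
  g
}

#' Classify studies by sample size
#'
#' A study is "large" when its combined case + control sample size is
#' strictly greater than \code{cutoff} subjects, else "small".
#'
#' @param set A \code{study_set}.
#' @param cutoff Combined-N threshold (default 1000).
#' @return Character vector, \code{"large"} or \code{"small"} per study.
#' @export
size_class <- function(set, cutoff = 1000) {
  ifelse(set$n_case + set$n_control > cutoff, "large", "small")
}

#' @export
print.study_set <- function(x, ...) {
  cat(sprintf("study_set '%s': %d studies, %d cases / %d controls\n",
              attr(x, "label"), nrow(x), sum(x$n_case), sum(x$n_control)))
  print(as.data.frame(x)[, c("study_id", "cancer_type", "ethnicity",
                             "control_source", "n_case", "n_control")],
        row.names = FALSE)
  invisible(x)
}
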