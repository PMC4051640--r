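# Packaged per-case study tables and their aggregation. The per-case cells
# are fixtures for the aggregation layer; only the summary rows (means, SDs,
# match rates) are recomputed.

FIXTURE_MD5 <- c(
  table4_overlap_operator.tsv = "5f87458713bd56992b68617f0a05a88e",
  table5_overlap_ample.tsv    = "03c5f58aab4357f6c95f6216d788aff9",
  table6_com_operator.tsv     = "931380876d2f9eb8ac7752886e5687d6",
  table8_ecs_operator.tsv     = "66e2ba9f3ae2696525f603198ebc9575",
  table9_ecs_ample.tsv        = "9159a98f2ec7703abfdca299c1896336")

#' Load the packaged per-case study tables
#'
#' Reads the five per-case tables shipped with the package: overlap
#' sensitivity/specificity under operator-chosen and AMPLE thresholds,
#' centre-of-mass distances under operator thresholds, and stimulation-site
#' distances under both thresholding schemes. Missing-data markers are kept
#' distinct: `"-"` (map unavailable) becomes NA with availability FALSE,
#' `"--"` (comparison impossible, no reference task map) becomes NA with a
#' separate flag. File checksums are verified on load.
#'
#' @return Named list of data.frames (`overlap_operator`, `overlap_ample`,
#'   `com_operator`, `ecs_operator`, `ecs_ample`). Numeric columns carry a
#'   companion attribute `"missing"`: a character matrix with entries `""`,
#'   `"-"` or `"--"`.
#' @export
load_fixture_tables <- function() {
  dir <- system.file("extdata", package = "motormap")
  out <- list()
  files <- c(overlap_operator = "table4_overlap_operator.tsv",
             overlap_ample = "table5_overlap_ample.tsv",
             com_operator = "table6_com_operator.tsv",
             ecs_operator = "table8_ecs_operator.tsv",
             ecs_ample = "table9_ecs_ample.tsv")
  for (nm in names(files)) {
    path <- file.path(dir, files[[nm]])
    if (!file.exists(path)) stop("missing fixture file ", files[[nm]])
    sum <- unname(tools::md5sum(path))
    if (sum != FIXTURE_MD5[[files[[nm]]]])
      stop("checksum mismatch for fixture ", files[[nm]])
    raw <- utils::read.delim(path, colClasses = "character",
                             check.names = FALSE)
    numcols <- setdiff(names(raw), c("case", "task", "point", "response"))
    miss <- matrix("", nrow(raw), length(numcols),
                   dimnames = list(NULL, numcols))
    df <- raw
    for (cc in numcols) {
      miss[, cc] <- ifelse(raw[[cc]] == "-", "-",
                           ifelse(raw[[cc]] == "--", "--", ""))
      df[[cc]] <- suppressWarnings(as.numeric(
        ifelse(raw[[cc]] %in% c("-", "--"), NA, raw[[cc]])))
    }
    for (cc in intersect(c("case", "point"), names(df)))
      df[[cc]] <- as.integer(df[[cc]])
    attr(df, "missing") <- miss
    out[[nm]] <- df
  }
  out
}

# mean/SD/grand summaries for one metric column of an overlap/CoM table
summarize_column <- function(tbl, column) {
  aggregate_summary(tbl[[column]], tbl$task)
}

#' Recompute the study summary rows from the per-case tables
#'
#' Aggregates the packaged per-case cells exactly as the study's tables do:
#' per-task mean/SD rows, grand (all-task) mean/SD rows, and for the
#' stimulation tables the per-method N, mean, SD and <7 / <10 mm match
#' rates. Values are unrounded; compare at the printed precision.
#'
#' @param fixtures output of [load_fixture_tables()] (loaded if omitted).
#' @return Nested list: `overlap_operator`, `overlap_ample`, `com_operator`
#'   (each a list of [aggregate_summary()] data.frames per metric column,
#'   plus `lesion_grand` for the CoM table: pooled mean over all four
#'   method columns), and `ecs_operator` / `ecs_ample` (per-method list of
#'   n, mean, sd, match_lt10, match_lt7).
#' @export
reproduce_summaries <- function(fixtures = load_fixture_tables()) {
  out <- list()
  for (nm in c("overlap_operator", "overlap_ample")) {
    tbl <- fixtures[[nm]]
    cols <- c("vol_tb", "vol_aroi", "vol_froi", "vol_ica",
              "alpha_aroi", "beta_aroi", "alpha_froi", "beta_froi",
              "alpha_ica", "beta_ica")
    out[[nm]] <- lapply(stats::setNames(cols, cols),
                        function(cc) summarize_column(tbl, cc))
  }
  tbl <- fixtures$com_operator
  cols <- c("d_aroi", "d_froi", "d_ica",
            "les_tb", "les_aroi", "les_froi", "les_ica")
  out$com_operator <- lapply(stats::setNames(cols, cols),
                             function(cc) summarize_column(tbl, cc))
  les <- unlist(tbl[c("les_tb", "les_aroi", "les_froi", "les_ica")])
  out$com_operator$lesion_grand <- aggregate_summary(as.numeric(les))
  for (nm in c("ecs_operator", "ecs_ample")) {
    tbl <- fixtures[[nm]]
    methods <- c(tb = "d_tb", aROI = "d_aroi", fROI = "d_froi",
                 ICA = "d_ica")
    out[[nm]] <- lapply(methods, function(cc) {
      d <- tbl[[cc]][!is.na(tbl[[cc]])]
      list(n = length(d), mean = mean(d), sd = stats::sd(d),
           match_lt10 = match_rate(d, 10), match_lt7 = match_rate(d, 7))
    })
  }
  out
}
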