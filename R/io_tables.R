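#' Read a HapMap-format recombination rate file
#'
#' Expects one header line and whitespace-delimited columns: position (1-based
#' bp), rate (cM/Mb), cumulative genetic map (cM). Positions must be strictly
#' increasing, rates non-negative, and the cumulative map non-decreasing.
#'
#' @param path rate file path.
#' @return a data.frame of class `recombination_map` with columns `pos`,
#'   `rate_cM_Mb`, `cum_cM`.
#' @export
read_recombination_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(utils::read.table(path, header = TRUE),
                  error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0L)
    stop("empty recombination map: ", path)
  if (ncol(raw) < 3L) stop("recombination map needs 3 columns (pos, rate, map)")
  map <- data.frame(pos = as.numeric(raw[[1]]), rate_cM_Mb = as.numeric(raw[[2]]),
                    cum_cM = as.numeric(raw[[3]]))
  recombination_map(map)
}

#' Construct / validate a recombination map
#'
#' @param map data.frame with columns `pos`, `rate_cM_Mb`, `cum_cM`.
#' @return validated `recombination_map`.
#' @export
recombination_map <- function(map) {
  map <- as.data.frame(map)
  stopifnot(all(c("pos", "rate_cM_Mb", "cum_cM") %in% names(map)))
  dec <- which(diff(map$pos) <= 0)
  if (length(dec))
    stop("positions not strictly increasing at line ", dec[1] + 1L)
  if (any(map$rate_cM_Mb < 0))
    stop("negative recombination rate at line ", which(map$rate_cM_Mb < 0)[1])
  if (any(diff(map$cum_cM) < -1e-9))
    stop("cumulative map decreases at line ", which(diff(map$cum_cM) < 0)[1] + 1L)
  class(map) <- c("recombination_map", "data.frame")
  map
}

#' Read a typed TSV table
#'
#' Reads a tab-separated file with header and coerces columns according to a
#' schema. Used for phenotype, covariate, expression and population tables.
#'
#' @param path TSV file path.
#' @param schema named character vector mapping required column names to types
#'   (`"character"`, `"numeric"`, `"integer"`); columns not in the schema are
#'   kept as read.
#' @param id_col optional column that must contain unique values (e.g. sample
#'   id); duplicates are an error.
#' @return data.frame with coerced columns.
#' @export
read_table <- function(path, schema = NULL, id_col = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    missing_cols <- setdiff(names(schema), names(tab))
    if (length(missing_cols))
      stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
    for (col in names(schema)) {
      tab[[col]] <- switch(schema[[col]],
        character = as.character(tab[[col]]),
        numeric   = as.numeric(tab[[col]]),
        integer   = as.integer(tab[[col]]),
        stop("unknown schema type: ", schema[[col]]))
    }
  }
  if (!is.null(id_col)) {
    if (!id_col %in% names(tab)) stop("missing required column(s): ", id_col)
    dup <- tab[[id_col]][duplicated(tab[[id_col]])]
    if (length(dup))
      stop("duplicate ", id_col, ": ", paste(unique(dup), collapse = ", "))
  }
  tab
}

#' Align a table's rows to the samples of a genotype matrix
#'
#' @param tab data.frame with an id column.
#' @param gm a [genotype_matrix].
#' @param id_col name of the id column (default `"id"`).
#' @return the table reordered to `gm$sample_ids`; ids in the table but not in
#'   `gm` are reported via a warning, samples absent from the table get `NA`
#'   rows.
#' @export
align_to_samples <- function(tab, gm, id_col = "id") {
  if (!id_col %in% names(tab)) stop("missing required column(s): ", id_col)
  extra <- setdiff(tab[[id_col]], gm$sample_ids)
  if (length(extra))
    warning(length(extra), " table id(s) not present in genotype matrix: ",
            paste(utils::head(extra, 5), collapse = ", "))
  idx <- match(gm$sample_ids, tab[[id_col]])
  out <- tab[idx, , drop = FALSE]
  out[[id_col]] <- gm$sample_ids
  rownames(out) <- NULL
  out
}

#' Read a trio pedigree table
#'
#' Accepts a 3-column TSV (`child`, `father`, `mother`, with header) or a
#' PLINK FAM-style file whose first four columns are family id, individual id,
#' father id, mother id (no header, `0` = missing parent).
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"fam"`.
#' @return a data.frame of class `pedigree_table` with columns `child`,
#'   `father`, `mother`.
#' @export
read_pedigree <- function(path, format = c("tsv", "fam")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    missing_cols <- setdiff(c("child", "father", "mother"), names(tab))
    if (length(missing_cols))
      stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
    ped <- tab[, c("child", "father", "mother")]
  } else {
    tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 4L) stop("FAM file needs at least 4 columns")
    ped <- data.frame(child = as.character(tab[[2]]),
                      father = as.character(tab[[3]]),
                      mother = as.character(tab[[4]]),
                      stringsAsFactors = FALSE)
    ped <- ped[ped$father != "0" & ped$mother != "0", , drop = FALSE]
  }
  pedigree_table(ped)
}

#' Construct / validate a pedigree table
#' @param ped data.frame with character columns `child`, `father`, `mother`.
#' @return validated `pedigree_table`.
#' @export
pedigree_table <- function(ped) {
  ped <- as.data.frame(ped)
  stopifnot(all(c("child", "father", "mother") %in% names(ped)))
  ped$child <- as.character(ped$child)
  ped$father <- as.character(ped$father)
  ped$mother <- as.character(ped$mother)
  self <- ped$child == ped$father | ped$child == ped$mother
  if (any(self))
    stop("child listed as its own parent: ",
         paste(ped$child[self], collapse = ", "))
  class(ped) <- c("pedigree_table", "data.frame")
  ped
}

#' Construct / validate a population table
#'
#' @param tab data.frame with columns `pop_code`, `n_samples`, and optionally
#'   `latitude_deg`, `longitude_deg`, `distance_km`, `allele_freq`.
#' @return validated data.frame of class `population_table`.
#' @export
population_table <- function(tab) {
  tab <- as.data.frame(tab)
  stopifnot(all(c("pop_code", "n_samples") %in% names(tab)))
  if (any(tab$n_samples < 1)) stop("n_samples must be >= 1")
  if ("allele_freq" %in% names(tab)) {
    f <- tab$allele_freq
    if (any(!is.na(f) & (f < 0 | f > 1)))
      stop("allele frequencies must lie in [0, 1]")
  }
  class(tab) <- c("population_table", "data.frame")
  tab
}
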