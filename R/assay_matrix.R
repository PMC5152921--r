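#' Coregulator constructs recognised by the assay annotation scheme
#'
#' The five exogenous coregulator constructs used in the functional assays:
#' wild-type human RXR (`RXR_WT`), the AF2-truncated RXR mutant (`RXR_AF2`),
#' and the three SRC/p160 coactivators (`SRC1`, `GRIP1`, `ACTR`).
#'
#' @format Character vector of length 5.
#' @export
COREGULATORS <- c("RXR_WT", "RXR_AF2", "SRC1", "GRIP1", "ACTR")

#' Construct an annotated assay-response matrix
#'
#' An `assay_matrix` holds one row per functional assay and one column per
#' receptor variant (species ortholog/paralog).  Each row is annotated with
#' the assay class (transient transactivation `TT` or mammalian two-hybrid
#' `M2H`), the ligand, and a presence/absence flag for each coregulator
#' construct -- the information rendered as a Pickett plot alongside the
#' heatmap in the original analyses.
#'
#' @param values Numeric matrix, assays in rows, receptor variants in
#'   columns.  Row and column names must be present and unique.
#' @param annotations Data frame with one row per assay, containing at least
#'   columns `assay_class` (`"TT"` or `"M2H"`), `ligand`, and one logical
#'   column per entry of [COREGULATORS].  An `assay` column, if present,
#'   must match `rownames(values)`.
#'
#' @return An object of class `assay_matrix`: a list with elements `values`
#'   (the numeric matrix) and `annotations` (the per-assay data frame).
#' @examples
#' m <- matrix(rnorm(8), 2, 4,
#'             dimnames = list(c("a1", "a2"), c("s1", "s2", "s3", "s4")))
#' ann <- data.frame(assay_class = c("TT", "M2H"), ligand = "LCA",
#'                   RXR_WT = c(TRUE, FALSE), RXR_AF2 = FALSE,
#'                   SRC1 = FALSE, GRIP1 = FALSE, ACTR = FALSE)
#' assay_matrix(m, ann)
#' @export
assay_matrix <- function(values, annotations) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have row (assay) and column (species) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate assay (row) names: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate species (column) names: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (anyNA(values))
    stop("`values` contains missing cells; fill them before assembly")
  annotations <- as.data.frame(annotations)
  if (nrow(annotations) != nrow(values))
    stop("`annotations` must have one row per assay")
  needed <- c("assay_class", "ligand", COREGULATORS)
  missing_cols <- setdiff(needed, names(annotations))
  if (length(missing_cols))
    stop("annotation columns missing: ", paste(missing_cols, collapse = ", "))
  for (g in COREGULATORS) {
    if (!is.logical(annotations[[g]]))
      stop("annotation flag `", g, "` must be logical (presence/absence)")
  }
  if (!all(annotations$assay_class %in% c("TT", "M2H")))
    stop("`assay_class` must be \"TT\" or \"M2H\"")
  if (!is.null(annotations$assay) &&
      !identical(as.character(annotations$assay), rownames(values)))
    stop("`annotations$assay` does not match rownames(values)")
  annotations$assay <- rownames(values)
  rownames(annotations) <- NULL
  structure(list(values = values, annotations = annotations),
            class = "assay_matrix")
}

#' @export
print.assay_matrix <- function(x, ...) {
  cat(sprintf("assay_matrix: %d assays x %d species\n",
              nrow(x$values), ncol(x$values)))
  cat("species:", paste(colnames(x$values), collapse = ", "), "\n")
  cls <- table(x$annotations$assay_class)
  cat("assay classes:",
      paste(sprintf("%s=%d", names(cls), cls), collapse = ", "), "\n")
  present <- vapply(COREGULATORS, function(g) sum(x$annotations[[g]]),
                    integer(1))
  cat("coregulator-annotated assays:",
      paste(sprintf("%s=%d", COREGULATORS, present), collapse = ", "), "\n")
  invisible(x)
}

#' Default synthetic assay roster
#'
#' The default 14-assay layout used by the synthetic-data generator: the
#' seven coregulator combinations `none`, `RXR_WT`, `RXR_AF2`, `SRC1`,
#' `GRIP1`, `ACTR` and `RXR_WT+SRC1`, each run as a transient
#' transactivation (TT) and as a mammalian two-hybrid (M2H) assay with
#' lithocholic acid as ligand.
#'
#' @param ligand Ligand annotation applied to every assay (default
#'   `"LCA"`).
#' @return Data frame with columns `assay`, `assay_class`, `ligand` and one
#'   logical presence/absence column per entry of [COREGULATORS].
#' @export
default_assay_layout <- function(ligand = "LCA") {
  combos <- list(none        = character(0),
                 RXR_WT      = "RXR_WT",
                 RXR_AF2     = "RXR_AF2",
                 SRC1        = "SRC1",
                 GRIP1       = "GRIP1",
                 ACTR        = "ACTR",
                 RXR_WT_SRC1 = c("RXR_WT", "SRC1"))
  rows <- list()
  for (cls in c("TT", "M2H")) {
    for (nm in names(combos)) {
      flags <- as.list(COREGULATORS %in% combos[[nm]])
      names(flags) <- COREGULATORS
      rows[[length(rows) + 1L]] <- data.frame(
        assay = paste(cls, ligand, nm, sep = "_"),
        assay_class = cls, ligand = ligand, flags,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Default species roster and reference partition
#'
#' The eight receptor variants of the study design and their two functional
#' clusters: `C1` (lamprey, bichir, skate VDR plus the zebrafish and medaka
#' beta paralogs) and `C2` (the zebrafish and medaka alpha paralogs plus
#' human VDR).
#'
#' @return Named list of two character vectors, `C1` and `C2`.
#' @export
default_species_groups <- function() {
  list(C1 = c("lVDR", "bVDR", "sVDR", "zfVDRb", "mVDRb"),
       C2 = c("zfVDRa", "mVDRa", "hVDR"))
}

#' Write / read an assay matrix as TSV plus a JSON annotation sidecar
#'
#' The matrix is stored as a tab-separated table (first column `assay`,
#' remaining columns one per species, full precision) and the row
#' annotations as a JSON sidecar next to it.
#'
#' @param x An [assay_matrix()].
#' @param path Path of the TSV file.
#' @param annotations_path Path of the JSON sidecar; defaults to `path`
#'   with its extension replaced by `.json`.
#' @return `write_assay_matrix` returns `path` invisibly;
#'   `read_assay_matrix` returns an [assay_matrix()].
#' @export
write_assay_matrix <- function(x, path,
                               annotations_path = sidecar_path(path)) {
  stopifnot(inherits(x, "assay_matrix"))
  df <- data.frame(assay = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(x$annotations, annotations_path,
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_assay_matrix
#' @export
read_assay_matrix <- function(path,
                              annotations_path = sidecar_path(path)) {
  if (!file.exists(path))
    stop("matrix file not found: ", path)
  if (!file.exists(annotations_path))
    stop("annotation sidecar not found; expected it at: ", annotations_path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "assay")
    stop("first column of ", path, " must be `assay`, found `",
         names(df)[1], "`")
  species <- names(df)[-1]
  if (anyDuplicated(species))
    stop("duplicate species column in ", path, ": ",
         paste(unique(species[duplicated(species)]), collapse = ", "))
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$assay
  ann <- jsonlite::read_json(annotations_path, simplifyVector = TRUE)
  ann <- as.data.frame(ann)
  for (g in COREGULATORS) ann[[g]] <- as.logical(ann[[g]])
  if (!identical(as.character(ann$assay), rownames(values)))
    stop("annotation sidecar assays do not match matrix rows")
  assay_matrix(values, ann)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}
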