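# Sample-sheet handling: the 16-library, 8-material experimental design.

.genotypes <- c("HIGH_BNF", "LOW_BNF")
.tissues <- c("ROOT", "SHOOT")
.conditions <- c("STALK", "HYDROPONIC")

# Accepted aliases for the enum vocabularies (case-insensitive).
.geno_alias <- c(
  HIGH_BNF = "HIGH_BNF", "SP70-1143" = "HIGH_BNF", SP = "HIGH_BNF", HIGH = "HIGH_BNF",
  LOW_BNF = "LOW_BNF", CHUNEE = "LOW_BNF", CH = "LOW_BNF", LOW = "LOW_BNF"
)
.tissue_alias <- c(ROOT = "ROOT", SHOOT = "SHOOT")
.cond_alias <- c(
  STALK = "STALK", HYDROPONIC = "HYDROPONIC", HYDROPONICS = "HYDROPONIC",
  HYDRO = "HYDROPONIC"
)

map_enum <- function(x, alias, what) {
  key <- toupper(trimws(as.character(x)))
  out <- unname(alias[key])
  if (anyNA(out)) {
    bad <- unique(key[is.na(out)])
    stop_canedet("unknown ", what, " value(s): ", paste(bad, collapse = ", "),
                 "; expected one of ", paste(unique(alias), collapse = "/"),
                 class = "canedet_vocabulary_error")
  }
  out
}

#' Construct and validate a sample sheet
#'
#' A sample sheet describes one sequencing library per row: which genotype
#' (high- or low-BNF), tissue (root or shoot), growth condition (germinated
#' stalk, i.e. naturally colonized, or bacteria-free hydroponics) and
#' biological replicate it corresponds to. The canonical design of the study
#' this package models has 16 libraries covering 8 plant materials (2 genotypes
#' x 2 tissues x 2 growth conditions) with 2 replicates each.
#'
#' @param library_id Character vector of unique library identifiers.
#' @param genotype `"HIGH_BNF"`/`"LOW_BNF"` (aliases `SP`, `SP70-1143`, `CH`,
#'   `Chunee` accepted, case-insensitive).
#' @param tissue `"ROOT"` or `"SHOOT"`.
#' @param growth_condition `"STALK"` or `"HYDROPONIC"`.
#' @param replicate Positive integer replicate index within a material.
#' @return A `data.frame` of class `sample_sheet` with columns `library_id`,
#'   `genotype`, `tissue`, `growth_condition`, `replicate` and a `material`
#'   column identifying the genotype x tissue x condition group.
#' @seealso [read_sample_sheet()], [canonical_design()]
#' @export
sample_sheet <- function(library_id, genotype, tissue, growth_condition, replicate) {
  library_id <- as.character(library_id)
  if (anyDuplicated(library_id)) {
    stop_canedet("duplicate library_id in sample sheet",
                 class = "canedet_duplicate_key_error")
  }
  replicate <- as.integer(replicate)
  if (any(is.na(replicate)) || any(replicate < 1)) {
    stop_canedet("replicate must be a positive integer",
                 class = "canedet_format_error")
  }
  sheet <- data.frame(
    library_id = library_id,
    genotype = map_enum(genotype, .geno_alias, "genotype"),
    tissue = map_enum(tissue, .tissue_alias, "tissue"),
    growth_condition = map_enum(growth_condition, .cond_alias, "growth_condition"),
    replicate = replicate,
    stringsAsFactors = FALSE
  )
  key <- with(sheet, paste(genotype, tissue, growth_condition, replicate, sep = "|"))
  if (anyDuplicated(key)) {
    stop_canedet("duplicate (genotype, tissue, growth_condition, replicate) design cell: ",
                 paste(unique(key[duplicated(key)]), collapse = ", "),
                 class = "canedet_duplicate_design_error")
  }
  sheet$material <- with(sheet, paste(genotype, tissue, growth_condition, sep = "."))
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}

#' Read a sample sheet from a TSV/CSV file
#'
#' The file must have columns `library_id`, `genotype`, `tissue`,
#' `growth_condition` and `replicate` (any order, case-insensitive enum
#' values). The delimiter is inferred from the extension (`.csv` = comma,
#' otherwise tab).
#'
#' @param path Path to the file.
#' @return A validated [sample_sheet()]; the number of distinct materials is
#'   reported via `message()`.
#' @export
read_sample_sheet <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "")
  names(raw) <- tolower(names(raw))
  need <- c("library_id", "genotype", "tissue", "growth_condition", "replicate")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop_canedet("sample sheet is missing column(s): ",
                 paste(missing_cols, collapse = ", "),
                 class = "canedet_format_error")
  }
  sheet <- sample_sheet(raw$library_id, raw$genotype, raw$tissue,
                        raw$growth_condition, raw$replicate)
  message(nrow(sheet), " libraries, ", length(unique(sheet$material)),
          " material group(s)")
  sheet
}

#' The canonical 16-library design
#'
#' Two genotypes x two tissues x two growth conditions x two replicates.
#' Library ids encode the cell, e.g. `SP.ROOT.STALK.1`.
#'
#' @return A [sample_sheet()] with 16 rows and 8 materials.
#' @export
canonical_design <- function() {
  grid <- expand.grid(
    replicate = 1:2,
    growth_condition = .conditions,
    tissue = .tissues,
    genotype = .genotypes,
    stringsAsFactors = FALSE
  )
  short <- c(HIGH_BNF = "SP", LOW_BNF = "CH")
  ids <- paste(short[grid$genotype], grid$tissue, grid$growth_condition,
               grid$replicate, sep = ".")
  sample_sheet(ids, grid$genotype, grid$tissue, grid$growth_condition, grid$replicate)
}

#' Write a sample sheet to TSV
#' @param sheet A [sample_sheet()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(
    sheet[c("library_id", "genotype", "tissue", "growth_condition", "replicate")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.sample_sheet <- function(x, ...) {
  cat("Sample sheet:", nrow(x), "libraries,",
      length(unique(x$material)), "material group(s)\n")
  print(as.data.frame(unclass(x)), ...)
  invisible(x)
}

# Libraries of one genotype, in sheet order.
libraries_of <- function(sheet, genotype) {
  sheet$library_id[sheet$genotype == genotype]
}
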