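# Tabular readers/writers. TSV throughout (gene symbols may contain commas),
# UTF-8, '.' decimal, 12 significant digits on write so round-trips are
# lossless at that precision.

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA, formatC(x, digits = 12, format = "g"))
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

.read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, fileEncoding = "UTF-8")
}

#' Write / read a sample design table
#' @param design a design `data.frame` (see [validate_design()]).
#' @param path file path (TSV).
#' @return `read_design` returns the validated design.
#' @export
write_design <- function(design, path) {
  .write_tsv(design, path)
  invisible(path)
}

#' @rdname write_design
#' @param genotypes,feedings vocabularies passed to [validate_design()].
#' @export
read_design <- function(path, genotypes = c("WT", "KO", "RE"),
                        feedings = c("AL", "TRF")) {
  d <- .read_tsv(path)
  d$is_reference <- as.logical(d$is_reference)
  validate_design(d, genotypes, feedings)
  d
}

#' Write an abundance matrix to TSV
#'
#' One row per protein: `protein_id`, `gene`, `n_peptides`, the three filter
#' flags, optional `secreted`, then one intensity column per sample.
#'
#' @param am an [abundance_matrix()].
#' @param path output file.
#' @export
write_abundance <- function(am, path) {
  stopifnot(inherits(am, "abund_matrix"))
  meta_cols <- intersect(c("protein_id", "gene", "n_peptides",
                           "flag_contaminant", "flag_decoy",
                           "flag_single_oxidized", "secreted"),
                         names(am$features))
  df <- cbind(am$features[meta_cols],
              as.data.frame(am$values, check.names = FALSE))
  .write_tsv(df, path)
  invisible(path)
}

#' Read an abundance matrix from TSV
#'
#' @param path input TSV written in the layout of [write_abundance()] (a
#'   proteinGroups-like table).
#' @param design sample design; every non-reference and reference sample in
#'   the design must have an intensity column.
#' @param scale scale tag of the stored values.
#' @return an [abundance_matrix()]; row order follows the file.
#' @export
read_abundance <- function(path, design, scale = c("raw", "log2_normalized")) {
  scale <- match.arg(scale)
  df <- .read_tsv(path)
  if (!"protein_id" %in% names(df))
    stop("abundance file is missing required column `protein_id`")
  want <- design$sample
  if (scale == "log2_normalized") want <- design$sample[!design$is_reference]
  missing_s <- setdiff(want, names(df))
  if (length(missing_s))
    stop("abundance file is missing design sample(s): ",
         paste(missing_s, collapse = ", "))
  if (anyDuplicated(df$protein_id))
    stop("duplicate protein ids in abundance file")
  have <- intersect(design$sample, names(df))
  vals <- as.matrix(df[have])
  rownames(vals) <- df$protein_id
  meta_cols <- setdiff(names(df), design$sample)
  feats <- df[meta_cols]
  for (fl in c("flag_contaminant", "flag_decoy", "flag_single_oxidized"))
    if (fl %in% names(feats)) feats[[fl]] <- as.logical(feats[[fl]])
  if ("secreted" %in% names(feats))
    feats$secreted <- as.logical(feats$secreted)
  abundance_matrix(vals, feats, scale = scale)
}

#' Write / read a long expression table
#' @param expression long `data.frame` with columns gene, genotype, zt, rep,
#'   value.
#' @param path file path (TSV).
#' @export
write_expression <- function(expression, path) {
  .write_tsv(expression, path)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- .read_tsv(path)
  need <- c("gene", "genotype", "zt", "rep", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("expression file is missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then members, tab-separated.
#' Duplicate members within a line are removed with a warning.
#'
#' @param path GMT file.
#' @return a named list of character vectors; names are set names, each
#'   vector carries a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields, got %d",
                   i, length(parts)))
    members <- parts[-(1:2)]
    if (anyDuplicated(members)) {
      warning(sprintf("GMT line %d ('%s'): duplicate members removed",
                      i, parts[1]))
      members <- unique(members)
    }
    attr(members, "description") <- parts[2]
    sets[[parts[1]]] <- members
  }
  sets
}

#' @rdname read_gmt
#' @param sets named list of member vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- nm
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
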