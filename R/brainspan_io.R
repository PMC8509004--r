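#' Collapse duplicate gene rows by arithmetic mean
#'
#' Expression matrices occasionally carry several rows for one gene symbol
#' (e.g. one per transcript annotation). Duplicates are collapsed to a single
#' row holding the per-sample arithmetic mean — a symmetric, order-independent
#' summary on the measurement scale.
#'
#' @param expr Numeric matrix, genes in rows (rownames are gene symbols),
#'   samples in columns.
#' @param quiet Suppress the message reporting how many rows were collapsed.
#' @return Matrix with unique rownames; column set unchanged.
#' @export
collapse_duplicates <- function(expr, quiet = FALSE) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (!anyDuplicated(rownames(expr))) return(expr)
  sym <- rownames(expr)
  n_dup <- sum(duplicated(sym))
  out <- rowsum(expr, group = sym, reorder = FALSE) /
    as.vector(table(factor(sym, levels = unique(sym))))
  if (!quiet) {
    message("collapse_duplicates: merged ", n_dup, " duplicate row(s) into ",
            nrow(out), " unique gene(s)")
  }
  out
}

#' Read an expression dataset in the BrainSpan CSV-triplet dialect
#'
#' The developmental-transcriptome download ships three files:
#' \code{expression_matrix.csv} (no header; first column a row index),
#' \code{columns_metadata.csv} (header \code{column_num, donor_id, donor_name,
#' age, gender, structure_acronym, structure_name}) and
#' \code{rows_metadata.csv} (header \code{row_num, ensembl_gene_id,
#' gene_symbol}). This reader parses age strings via [parse_age()], drops
#' prenatal (\code{pcw}) samples, maps structure acronyms onto the 16-code
#' region vocabulary (unmapped acronyms are dropped with a warning, so atlas
#' variants with extra structures still load), and collapses duplicate gene
#' symbols by [collapse_duplicates()].
#'
#' @param dir Directory holding the triplet under the canonical file names;
#'   alternatively pass the three paths explicitly.
#' @param expression_csv,columns_csv,rows_csv Explicit file paths (override
#'   \code{dir}).
#' @param map Acronym-to-region lookup as returned by [region_map()].
#' @param quiet Suppress progress messages.
#' @return List of class \code{"brainspan_data"}: \code{expr} (numeric matrix,
#'   genes x samples, rownames gene symbols) and \code{samples} (data.frame
#'   with \code{sample_id, donor_id, age_years, region, sex}, one row per
#'   expression column).
#' @export
read_brainspan <- function(dir = NULL,
                           expression_csv = file.path(dir, "expression_matrix.csv"),
                           columns_csv = file.path(dir, "columns_metadata.csv"),
                           rows_csv = file.path(dir, "rows_metadata.csv"),
                           map = region_map(),
                           quiet = FALSE) {
  for (f in c(expression_csv, columns_csv, rows_csv)) {
    if (!file.exists(f)) stop("missing input file: ", f)
  }
  cols <- utils::read.csv(columns_csv, stringsAsFactors = FALSE)
  rows <- utils::read.csv(rows_csv, stringsAsFactors = FALSE)
  need <- c("column_num", "donor_id", "age", "gender", "structure_acronym")
  if (!all(need %in% names(cols))) {
    stop("columns_metadata lacks field(s): ",
         paste(setdiff(need, names(cols)), collapse = ", "))
  }
  if (!"gene_symbol" %in% names(rows)) {
    stop("rows_metadata lacks field 'gene_symbol'")
  }
  raw <- utils::read.csv(expression_csv, header = FALSE,
                         stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty expression matrix: ", expression_csv)
  expr <- as.matrix(raw[, -1, drop = FALSE])  # first column = row index
  storage.mode(expr) <- "double"
  if (nrow(expr) != nrow(rows)) {
    stop("dimension mismatch: ", nrow(expr), " expression rows vs ",
         nrow(rows), " rows_metadata records")
  }
  if (ncol(expr) != nrow(cols)) {
    stop("dimension mismatch: ", ncol(expr), " expression columns vs ",
         nrow(cols), " columns_metadata records")
  }
  rownames(expr) <- rows$gene_symbol

  age <- parse_age(cols$age)
  keep_age <- !is.na(age)
  if (!any(keep_age)) stop("all samples are prenatal; nothing to analyse")
  region <- unname(map[cols$structure_acronym])
  keep_reg <- !is.na(region)
  if (any(!keep_reg) && !quiet) {
    warning("dropping ", sum(!keep_reg), " sample(s) with unmapped ",
            "structure acronym(s): ",
            paste(unique(cols$structure_acronym[!keep_reg]), collapse = ", "))
  }
  keep <- keep_age & keep_reg
  if (!quiet && any(keep_age & !keep)) {
    # prenatal drops are routine; only acronym drops warn above
  }
  samples <- data.frame(
    sample_id = sprintf("s%04d", cols$column_num[keep]),
    donor_id = as.character(cols$donor_id[keep]),
    age_years = age[keep],
    region = region[keep],
    sex = ifelse(toupper(substr(cols$gender[keep], 1, 1)) == "F", "F", "M"),
    stringsAsFactors = FALSE
  )
  expr <- expr[, keep, drop = FALSE]
  colnames(expr) <- samples$sample_id
  expr <- collapse_duplicates(expr, quiet = quiet)
  structure(list(expr = expr, samples = samples), class = "brainspan_data")
}

#' Write an expression dataset in the BrainSpan CSV-triplet dialect
#'
#' Serialises a matrix + sample table to \code{expression_matrix.csv},
#' \code{columns_metadata.csv} and \code{rows_metadata.csv} so that
#' [read_brainspan()] recovers them. Ages are written as the nearest
#' representable \code{"N mos"}/\code{"N yrs"} string (see [format_age()]).
#'
#' @param expr Numeric matrix, genes x samples, rownames gene symbols.
#' @param samples data.frame with \code{sample_id, donor_id, age_years,
#'   region, sex}; one row per matrix column, in column order.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_brainspan <- function(expr, samples, dir) {
  stopifnot(is.matrix(expr), nrow(samples) == ncol(expr))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cols <- data.frame(
    column_num = seq_len(nrow(samples)),
    donor_id = samples$donor_id,
    donor_name = samples$donor_id,
    age = format_age(samples$age_years),
    gender = samples$sex,
    structure_acronym = samples$region,
    structure_name = samples$region,
    stringsAsFactors = FALSE
  )
  rows <- data.frame(
    row_num = seq_len(nrow(expr)),
    ensembl_gene_id = paste0("SYN_", rownames(expr)),
    gene_symbol = rownames(expr),
    stringsAsFactors = FALSE
  )
  fe <- file.path(dir, "expression_matrix.csv")
  fc <- file.path(dir, "columns_metadata.csv")
  fr <- file.path(dir, "rows_metadata.csv")
  utils::write.table(cbind(seq_len(nrow(expr)), expr), fe, sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.csv(cols, fc, row.names = FALSE, quote = FALSE)
  utils::write.csv(rows, fr, row.names = FALSE, quote = FALSE)
  invisible(c(expression = fe, columns = fc, rows = fr))
}

#' Sub-structural compartment vocabulary
#'
#' Cilia genes are annotated to the organelle's structural and functional
#' components: the axoneme (the 9+0 microtubule shaft), basal body (anchoring
#' base), transition zone (the gate between them), the motor and transport
#' machinery (kinesin, dynein, IFT-A, IFT-B, BBSome), membrane and signalling
#' classes (ciliary membrane, GPCR), and broader localisations (Golgi,
#' cytosol, nucleus, mitochondria, centrosome). Genes of unknown localisation
#' fall in \code{"other"}.
#'
#' @return Character vector of the 16 compartment labels.
#' @export
cilia_compartments <- function() {
  c("axoneme", "basal body", "transition zone", "kinesin", "dynein",
    "IFT-A", "IFT-B", "BBSome", "Golgi", "cytosol", "nucleus",
    "ciliary membrane", "GPCR", "mitochondria", "centrosome", "other")
}

#' Load a cilia gene panel with compartment annotations
#'
#' Reads a two-column TSV (header \code{symbol}, \code{compartments};
#' compartments semicolon-separated) into a validated annotation table.
#' Missing or empty compartments default to \code{"other"}; labels outside
#' [cilia_compartments()] raise an error; byte-identical duplicate records
#' are dropped, while a symbol repeated with conflicting compartments is an
#' error.
#'
#' @param path Path to the TSV. Defaults to the packaged synthetic stand-in
#'   panel of 445 genes (real cilia gene symbols seeded per compartment,
#'   remainder synthetic placeholders).
#' @return data.frame with columns \code{symbol} (character, unique) and
#'   \code{compartments} (list of character vectors, each non-empty).
#' @export
#' @examples
#' panel <- load_gene_list()
#' nrow(panel)  # 445
load_gene_list <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cilia_genes_synthetic.tsv",
                        package = "ciliascreen")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!"symbol" %in% names(tab)) stop("gene list lacks a 'symbol' column")
  if (!"compartments" %in% names(tab)) tab$compartments <- ""
  tab$symbol <- trimws(tab$symbol)
  if (any(tab$symbol == "")) stop("gene list contains empty symbol(s)")
  tab <- unique(tab[c("symbol", "compartments")])
  dup <- duplicated(tab$symbol)
  if (any(dup)) {
    stop("conflicting compartment annotations for: ",
         paste(unique(tab$symbol[dup]), collapse = ", "))
  }
  comp <- strsplit(tab$compartments, ";", fixed = TRUE)
  comp <- lapply(comp, function(z) {
    z <- trimws(z[nzchar(trimws(z))])
    if (!length(z)) "other" else unique(z)
  })
  bad <- setdiff(unique(unlist(comp)), cilia_compartments())
  if (length(bad)) {
    stop("unknown compartment label(s): ", paste(bad, collapse = ", "))
  }
  data.frame(symbol = tab$symbol, compartments = I(comp),
             stringsAsFactors = FALSE)
}
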