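#' Encode expression relative to the per-gene median
#'
#' Maps an expression value onto a 5-level code mirroring GISTIC-thresholded
#' copy-number calls, using the gene's median expression `m` across patients
#' as the reference: below 0.05*m is -2, from 0.05*m up to (excluding)
#' 0.75*m is -1, above 1.25*m up to (including) 1.75*m is 1, above 1.75*m is
#' 2, and the neutral band around the median (including both endpoints
#' 0.75*m and 1.25*m) is 0. The bands partition the axis; boundary
#' membership follows the low-side-closed / high-side-closed convention so
#' the median itself always codes 0. A zero median is a degenerate gene and
#' codes 0 everywhere.
#'
#' @param x numeric vector of non-negative expression values.
#' @param m the gene's median expression over the same sample set (scalar).
#' @return integer vector of codes in {-2,-1,0,1,2}; NA in, NA out.
#' @examples
#' encode_relative_expression(c(0.01, 0.5, 1, 1.5, 3), m = 1)
#' @export
encode_relative_expression <- function(x, m) {
  stopifnot(length(m) == 1L)
  code <- rep(NA_integer_, length(x))
  ok <- !is.na(x)
  if (is.na(m) || m == 0) {
    code[ok] <- 0L
    return(code)
  }
  r <- x[ok] / m
  code[ok] <- ifelse(r < 0.05, -2L,
              ifelse(r < 0.75, -1L,
              ifelse(r <= 1.25, 0L,
              ifelse(r <= 1.75, 1L, 2L))))
  code
}

#' Encode a whole expression matrix
#'
#' Computes each gene's median over non-missing values across patients and
#' encodes every cell with [encode_relative_expression()]. All-missing rows
#' stay missing; zero-median rows code 0.
#'
#' @param expr gene x sample numeric matrix.
#' @return integer matrix of the same shape with codes in {-2,-1,0,1,2}.
#' @export
encode_expression_matrix <- function(expr) {
  stopifnot(is.matrix(expr), length(expr) > 0L)
  medians <- apply(expr, 1L, stats::median, na.rm = TRUE)  # NaN for all-NA rows
  codes <- matrix(NA_integer_, nrow(expr), ncol(expr),
                  dimnames = dimnames(expr))
  degenerate <- 0L
  for (i in seq_len(nrow(expr))) {
    m <- medians[i]
    if (is.na(m)) next                       # all-missing gene row
    if (m == 0) degenerate <- degenerate + 1L
    codes[i, ] <- encode_relative_expression(expr[i, ], m)
  }
  if (degenerate > 0L) {
    message(degenerate, " genes have zero median expression; coded 0")
  }
  attr(codes, "gene_symbols") <- attr(expr, "gene_symbols")
  codes
}

#' Validate copy-number calls against expression (GECNAV)
#'
#' For every gene x sample cell: a nonzero thresholded CNA call is kept only
#' if the encoded expression status of that gene in that sample has the same
#' (nonzero) sign, in which case the cell takes the expression code itself
#' (so an amplification call of 2 can become 1); discordant or zero
#' expression zeroes the cell, and zero CNA stays zero. Genes with no row in
#' either expression matrix pass through unchanged, as do samples absent
#' from the expression data. Genes are routed to the miRNA code matrix when
#' their symbol appears there, otherwise matched to the mRNA codes by Entrez
#' id.
#'
#' @param cna gene x sample CNA matrix (Entrez rownames, symbols in
#'   `attr(, "gene_symbols")`).
#' @param expr_codes encoded mRNA expression matrix from
#'   [encode_expression_matrix()] (Entrez rownames).
#' @param mirna_codes optional encoded miRNA matrix (miRNA-name rownames).
#' @return matrix shaped like `cna` with values in {-2,-1,0,1,2}.
#' @export
validate_cna <- function(cna, expr_codes, mirna_codes = NULL) {
  out <- cna
  symbols <- attr(cna, "gene_symbols")
  if (is.null(symbols)) symbols <- stats::setNames(rownames(cna), rownames(cna))

  fill_from <- function(codes, gene_rows_codes, gene_rows_out) {
    # column match by shared barcode prefix
    col_idx <- match_barcodes(colnames(cna), colnames(codes))
    have_col <- !is.na(col_idx)
    if (!all(have_col)) {
      message(sum(!have_col), " CNA samples absent from expression data; calls passed through")
    }
    for (k in seq_along(gene_rows_out)) {
      i <- gene_rows_out[k]
      code_row <- codes[gene_rows_codes[k], col_idx[have_col]]
      cna_row <- cna[i, have_col]
      new <- ifelse(is.na(cna_row) | cna_row == 0, 0L,
             ifelse(!is.na(code_row) & code_row != 0 &
                    sign(code_row) == sign(cna_row), code_row, 0L))
      # missing CNA cells stay missing
      new[is.na(cna_row)] <- NA_integer_
      out[i, have_col] <<- new
    }
  }

  in_mirna <- if (is.null(mirna_codes)) rep(FALSE, nrow(cna)) else
    unname(symbols[rownames(cna)]) %in% rownames(mirna_codes)
  in_mrna <- !in_mirna & rownames(cna) %in% rownames(expr_codes)

  if (any(in_mrna)) {
    rows <- which(in_mrna)
    fill_from(expr_codes, match(rownames(cna)[rows], rownames(expr_codes)), rows)
  }
  if (any(in_mirna)) {
    rows <- which(in_mirna)
    fill_from(mirna_codes, match(unname(symbols[rownames(cna)[rows]]),
                                 rownames(mirna_codes)), rows)
  }
  storage.mode(out) <- "integer"
  attr(out, "gene_symbols") <- symbols
  out
}

#' Run the GECNAV pipeline
#'
#' Encodes the mRNA and miRNA expression matrices and validates the CNA
#' matrix against them.
#'
#' @param cna,expr,mirna matrices as returned by [read_cna_matrix()],
#'   [read_expression_matrix()], [read_mirna_matrix()] (already filtered to
#'   primary, whitelisted samples).
#' @return the validated CNA matrix.
#' @export
run_gecnav <- function(cna, expr, mirna = NULL) {
  expr_codes <- encode_expression_matrix(expr)
  mirna_codes <- if (!is.null(mirna)) encode_expression_matrix(mirna) else NULL
  validate_cna(cna, expr_codes, mirna_codes)
}
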