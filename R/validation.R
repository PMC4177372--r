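# Quantification calculators for the wet-lab validation assays that
# accompany a capture-seq screen: bisulfite-sequencing clone matrices,
# methylation-sensitive restriction enzyme qPCR, and relative expression by
# the 2^-ddCt model.

# normalise clone calls to 1 (methylated) / 0 (unmethylated) / NA (missing)
.bsp_calls <- function(m) {
  if (is.data.frame(m)) m <- as.matrix(m)
  if (is.character(m)) {
    v <- toupper(m)
    out <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
    out[v %in% c("M", "METHYLATED", "1")] <- 1
    out[v %in% c("U", "UNMETHYLATED", "0")] <- 0
    bad <- !(v %in% c("M", "METHYLATED", "1", "U", "UNMETHYLATED", "0",
                      "", ".", "NA")) & !is.na(v)
    if (any(bad))
      stop("unrecognised clone call '", v[which(bad)[1]], "'")
    out
  } else {
    if (!all(m %in% c(0, 1, NA)))
      stop("numeric clone calls must be 0, 1 or NA")
    m * 1
  }
}

#' Methylation fractions from a BSP clone matrix
#'
#' Rows are sequenced clones, columns CpG sites; calls are methylated /
#' unmethylated / missing. Per-CpG fractions ignore missing calls; the
#' overall fraction pools every informative call. Amplicons sequenced to
#' fewer than \code{min_clones} clones are flagged incomplete (the standard
#' quality rule is at least five clones per reaction).
#'
#' @param matrix Clone-by-CpG matrix: numeric 0/1/NA or characters
#'   M/U/methylated/unmethylated/missing.
#' @param min_clones Completeness threshold (default 5).
#' @return List with \code{per_cpg} (NA where a site has no informative
#'   call), \code{overall}, \code{n_clones}, \code{n_calls} and
#'   \code{complete}.
#' @export
bsp_fraction <- function(matrix, min_clones = 5) {
  calls <- .bsp_calls(matrix)
  if (length(calls) == 0 || nrow(calls) < 1 || ncol(calls) < 1)
    stop("empty clone matrix")
  informative <- colSums(!is.na(calls))
  per_cpg <- ifelse(informative > 0,
                    colSums(calls == 1, na.rm = TRUE) / informative,
                    NA_real_)
  n_calls <- sum(!is.na(calls))
  overall <- if (n_calls > 0) sum(calls == 1, na.rm = TRUE) / n_calls
             else NA_real_
  list(per_cpg = per_cpg, overall = overall, n_clones = nrow(calls),
       n_calls = n_calls, complete = nrow(calls) >= min_clones)
}

#' Methylated fraction from MSRE-qPCR Ct values
#'
#' Methylated templates resist a methylation-sensitive digest, so the
#' surviving (methylated) fraction is \code{2^-(Ct_digested - Ct_mock)}: no
#' shift means fully methylated, each extra cycle halves the surviving
#' fraction. Values outside [0, 1] (digested amplifying earlier than mock,
#' ordinary qPCR noise) are clamped with a warning.
#'
#' @param ct_digested,ct_mock Ct values (cycles) of digested and
#'   mock-digested reactions; vectorised.
#' @return Methylated fraction(s) in [0, 1].
#' @export
msre_methylation <- function(ct_digested, ct_mock) {
  if (anyNA(ct_digested) || anyNA(ct_mock))
    stop("missing Ct value")
  if (any(ct_digested <= 0) || any(ct_mock <= 0))
    stop("Ct values must be positive")
  f <- 2^-(ct_digested - ct_mock)
  if (any(f > 1))
    warning("ct_digested < ct_mock: fraction clamped to 1", call. = FALSE)
  pmin(pmax(f, 0), 1)
}

#' Relative expression by the 2^-ddCt model
#'
#' dCt = Ct_target - Ct_reference per replicate; replicate dCts are averaged
#' per condition (arithmetic mean of Ct, i.e. geometric mean of quantities)
#' and ddCt = mean dCt(treated) - mean dCt(control); fold change =
#' \code{2^-ddCt}. With \code{per_replicate = TRUE} the fold change is
#' instead the mean of per-replicate fold changes against the control mean
#' dCt.
#'
#' @param ct data.frame with columns \code{condition}, \code{target_ct},
#'   \code{reference_ct} (one row per replicate).
#' @param treated_label,control_label Condition labels to compare.
#' @param per_replicate Alternative replicate aggregation (default FALSE).
#' @return List with \code{fold_change}, \code{ddct}, and per-condition
#'   mean/sd/n of dCt.
#' @export
ddct_expression <- function(ct, treated_label, control_label,
                            per_replicate = FALSE) {
  need <- c("condition", "target_ct", "reference_ct")
  if (!all(need %in% names(ct)))
    stop("ct table needs columns: ", paste(need, collapse = ", "))
  if (anyNA(ct$target_ct) || anyNA(ct$reference_ct))
    stop("missing Ct value")
  if (any(ct$target_ct <= 0) || any(ct$reference_ct <= 0))
    stop("Ct values must be positive")
  pick <- function(label) {
    rows <- ct[ct$condition == label, , drop = FALSE]
    if (nrow(rows) == 0) stop("condition '", label, "' absent from table")
    rows$target_ct - rows$reference_ct
  }
  dct_t <- pick(treated_label)
  dct_c <- pick(control_label)
  ddct <- mean(dct_t) - mean(dct_c)
  fold <- if (per_replicate) mean(2^-(dct_t - mean(dct_c))) else 2^-ddct
  list(fold_change = fold, ddct = ddct,
       treated = list(mean_dct = mean(dct_t), sd_dct = stats::sd(dct_t),
                      n = length(dct_t)),
       control = list(mean_dct = mean(dct_c), sd_dct = stats::sd(dct_c),
                      n = length(dct_c)),
       per_replicate = per_replicate)
}

#' Read a Ct table
#'
#' @param path TSV with header columns \code{sample_id} (optional),
#'   \code{condition}, \code{target_ct}, \code{reference_ct}.
#' @return data.frame suitable for \code{\link{ddct_expression}}.
#' @export
read_ct_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  need <- c("condition", "target_ct", "reference_ct")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("Ct table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  tab
}

#' Read a BSP clone matrix
#'
#' @param path TSV; rows are clones, columns CpG sites, cells M/U (or 0/1),
#'   empty or NA for missing. A header row of site labels and a first
#'   column of clone ids are accepted.
#' @return Character matrix for \code{\link{bsp_fraction}}.
#' @export
read_bsp_matrix <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, row.names = 1,
                    stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = c("NA", "", "."))
  as.matrix(tab)
}
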