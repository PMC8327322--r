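VARIANT_COLUMNS <- c("gene", "protein_position", "cohort", "carrier_count")

#' Read a tab-separated variant table
#'
#' Parses the native TSV dialect (header columns \code{gene},
#' \code{protein_position}, \code{cohort}, \code{carrier_count}, optional
#' \code{popmax_af}, optional \code{acmg_class}, any further columns kept
#' as in-silico scores; lines starting with \code{#} are comments), groups
#' rows by gene and returns one \linkS4class{GeneDataset} per gene.
#'
#' @param path file path.
#' @param proteinLengths named integer vector (or 2-column data.frame
#'   gene/length) giving each gene's protein length.
#' @param nCases,nControls cohort sizes, either single integers shared by
#'   all genes or named vectors keyed by gene.
#' @param afThreshold optional popmax-AF filter applied on read (strict
#'   upper bound; \code{NULL} keeps everything).
#' @return named list of \linkS4class{GeneDataset} objects.
#' @export
readVariantTable <- function(path, proteinLengths, nCases, nControls,
                             afThreshold = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(VARIANT_COLUMNS, names(tab))
  if (length(miss))
    stop("variant table is missing required column(s): ",
         paste(miss, collapse = ", "))
  posNum <- suppressWarnings(as.numeric(tab$protein_position))
  bad <- which(is.na(posNum) | posNum != floor(posNum))
  if (length(bad))
    stop("non-integer protein_position at data line(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (is.data.frame(proteinLengths))
    proteinLengths <- stats::setNames(as.integer(proteinLengths[[2]]),
                                      proteinLengths[[1]])
  if (!"popmax_af" %in% names(tab)) tab$popmax_af <- NA_real_
  lookup <- function(x, gene) {
    if (length(x) == 1L && is.null(names(x))) x
    else if (gene %in% names(x)) x[[gene]]
    else stop("no entry for gene ", gene)
  }
  out <- lapply(split(tab, tab$gene), function(g) {
    gene <- g$gene[1]
    if (!gene %in% names(proteinLengths))
      stop("no protein length supplied for gene ", gene)
    extra <- setdiff(names(g), c(VARIANT_COLUMNS, "popmax_af"))
    v <- data.frame(position = as.integer(g$protein_position),
                    cohort = g$cohort,
                    carrier_count = as.integer(g$carrier_count),
                    popmax_af = as.numeric(g$popmax_af),
                    stringsAsFactors = FALSE)
    for (cn in extra) {
      v[[if (cn == "acmg_class") "label" else cn]] <- g[[cn]]
    }
    if (!is.null(afThreshold)) v <- filterRare(v, afThreshold)
    GeneDataset(gene = gene,
                proteinLength = proteinLengths[[gene]],
                nCases = lookup(nCases, gene),
                nControls = lookup(nControls, gene),
                variants = v)
  })
  out
}

#' Write GeneDatasets to the native TSV dialect
#'
#' Emits one row per variant record with the documented column contract,
#' preceded by provenance comment lines (package version and any config
#' echo).
#'
#' @param datasets a \linkS4class{GeneDataset} or list of them.
#' @param path output file.
#' @param config optional named list echoed into the provenance header.
#' @return invisibly, the written data.frame.
#' @export
writeVariantTable <- function(datasets, path, config = NULL) {
  if (is(datasets, "GeneDataset")) datasets <- list(datasets)
  rows <- lapply(datasets, function(ds) {
    v <- ds@variants
    base <- data.frame(gene = rep(ds@gene, nrow(v)),
                       protein_position = v$position, cohort = v$cohort,
                       carrier_count = v$carrier_count,
                       popmax_af = v$popmax_af, stringsAsFactors = FALSE)
    extra <- setdiff(names(v),
                     c("position", "cohort", "carrier_count", "popmax_af"))
    for (cn in extra)
      base[[if (cn == "label") "acmg_class" else cn]] <- v[[cn]]
    base
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenanceHeader(config), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tab)
}

provenanceHeader <- function(config = NULL) {
  lines <- sprintf("# cbkit %s",
                   as.character(utils::packageVersion("cbkit")))
  if (!is.null(config))
    lines <- c(lines, sprintf("# config: %s = %s", names(config),
                              vapply(config, function(x)
                                paste(format(x), collapse = ","),
                                character(1))))
  lines
}

#' Read per-residue coverage profiles
#'
#' Parses a TSV with columns \code{gene}, \code{position}, \code{cohort}
#' and \code{prop_10x} (the mean proportion of samples with >= 10x depth,
#' in (0, 1]) into dense per-residue vectors. Residues absent from the
#' file default to full coverage (1.0) with a message; duplicated
#' (gene, position, cohort) rows are an error.
#'
#' @param path file path.
#' @param proteinLengths named integer vector of protein lengths.
#' @return nested list: \code{out[[gene]]$case} / \code{$control}.
#' @export
readCoverage <- function(path, proteinLengths) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  req <- c("gene", "position", "cohort", "prop_10x")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("coverage table is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (any(tab$prop_10x <= 0 | tab$prop_10x > 1))
    stop("prop_10x values must lie in (0, 1]")
  key <- paste(tab$gene, tab$position, tab$cohort)
  if (anyDuplicated(key))
    stop("duplicate (gene, position, cohort) coverage rows")
  if (is.data.frame(proteinLengths))
    proteinLengths <- stats::setNames(as.integer(proteinLengths[[2]]),
                                      proteinLengths[[1]])
  out <- lapply(split(tab, tab$gene), function(g) {
    gene <- g$gene[1]
    if (!gene %in% names(proteinLengths))
      stop("no protein length supplied for gene ", gene)
    L <- proteinLengths[[gene]]
    prof <- list()
    for (ch in unique(g$cohort)) {
      gg <- g[g$cohort == ch, , drop = FALSE]
      if (any(gg$position < 1 | gg$position > L))
        stop("coverage position outside [1, L] for gene ", gene)
      v <- rep(1, L)
      v[gg$position] <- gg$prop_10x
      if (nrow(gg) < L)
        message(sprintf(
          "coverage for %s/%s: %d of %d residues unlisted, defaulting to 1.0",
          gene, ch, L - nrow(gg), L))
      prof[[ch]] <- v
    }
    prof
  })
  out
}

#' Run configuration
#'
#' Bundles the tunable thresholds of the toolkit with their defaults:
#' the rare-variant popmax-AF threshold, the family-wise alpha, the
#' binning heuristic floor, GAM basis dimension / smoothing criterion /
#' coverage window, simulator defaults and the master seed. Serializable
#' to a plain-text YAML file.
#'
#' @param ... overrides of the default fields.
#' @return named list of configuration values.
#' @export
runConfig <- function(...) {
  cfg <- list(
    af_threshold = 1e-4,
    alpha_family = 0.05,
    bin_k_min = 2L,
    gam_basis_dim = 10L,
    gam_smoothing = "REML",
    coverage_window = 15L,
    sim_benign_carrier_rate = 0.06,
    sim_pathogenic_carrier_fraction = 0.2,
    sim_penetrance_or = 50,
    seed = 1L,
    out_dir = "."
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$af_threshold > 0, cfg$af_threshold < 1,
            cfg$alpha_family > 0, cfg$alpha_family < 1)
  cfg
}

#' @rdname runConfig
#' @param cfg a configuration list.
#' @param path YAML file path.
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
  do.call(runConfig, yaml::read_yaml(path))
}
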