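# Orchestration: read -> recode -> search -> consensus -> supports ->
# synapomorphies -> report, with a flat config and deterministic seeding.

#' Analysis configuration
#'
#' Flat key/value settings for [run_analysis()].  The defaults mirror the
#' published search protocol for the Promyliobatis matrix: 1000 random
#' addition replicates with TBR swapping, holding one tree per step, all
#' characters unordered with equal weight, bootstrap with 1000
#' replicates.  Every default that fills a gap left by the published
#' methods (outgroup, collapse rule, CI inclusion mode, per-replicate
#' bootstrap search effort) is echoed in the report.
#'
#' @param method search strategy (see [mp_search()])
#' @param replicates random addition sequences for the heuristic search
#' @param hold partial trees held per addition step
#' @param seed master seed; all stages derive their randomness from it
#' @param max_trees tie cap
#' @param ordered_all treat every character as ordered (the published
#'   ordered-variant analysis)
#' @param collapse collapse zero-minimum-length branches before counting
#'   distinct trees
#' @param ci_include_uninformative include parsimony-uninformative
#'   characters in ensemble CI/RI
#' @param outgroup tip label used to root for synapomorphy polarity
#'   (default: first matrix taxon, with a warning)
#' @param bremer,bremer_cap compute Bremer supports; censor at cap
#' @param bootstrap,bootstrap_reps,bootstrap_search_replicates compute
#'   character bootstrap; pseudoreplicate count; RAS replicates per
#'   pseudoreplicate
#' @param apomorphies map synapomorphies on the first MPT
#' @param recodings optional [recoding_ledger()] (or TSV path) applied
#'   before analysis
#' @return a list of class `analysis_config`
#' @export
analysis_config <- function(method = "auto", replicates = 1000L, hold = 1L,
                            seed = 1L, max_trees = 10000L,
                            ordered_all = FALSE, collapse = TRUE,
                            ci_include_uninformative = TRUE,
                            outgroup = NULL,
                            bremer = TRUE, bremer_cap = 20L,
                            bootstrap = FALSE, bootstrap_reps = 1000L,
                            bootstrap_search_replicates = 10L,
                            apomorphies = TRUE,
                            recodings = NULL) {
  structure(list(method = method, replicates = as.integer(replicates),
                 hold = as.integer(hold), seed = as.integer(seed),
                 max_trees = as.integer(max_trees),
                 ordered_all = ordered_all, collapse = collapse,
                 ci_include_uninformative = ci_include_uninformative,
                 outgroup = outgroup,
                 bremer = bremer, bremer_cap = as.integer(bremer_cap),
                 bootstrap = bootstrap,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 bootstrap_search_replicates =
                   as.integer(bootstrap_search_replicates),
                 apomorphies = apomorphies, recodings = recodings),
            class = "analysis_config")
}

#' Ordered-characters variant of a configuration
#'
#' Returns the same configuration with every character flagged ordered
#' (the published supplementary variant).  Idempotent.
#'
#' @param config an [analysis_config()]
#' @return the modified configuration
#' @export
variant_ordered <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  config$ordered_all <- TRUE
  config
}

read_matrix_auto <- function(x, format = c("auto", "nexus", "tnt")) {
  format <- match.arg(format)
  if (inherits(x, "char_matrix")) return(x)
  txt <- slurp_text(x, "")   # accepts a path or literal text
  if (format == "auto") {
    format <- if (grepl("(?i)#NEXUS", txt, perl = TRUE)) "nexus"
    else if (grepl("(?i)xread", txt, perl = TRUE)) "tnt"
    else stop("cannot detect matrix format (expected NEXUS or TNT xread)")
  }
  if (format == "nexus") read_nexus(txt) else read_tnt(txt)
}

#' Run the full parsimony workflow
#'
#' Reads (or accepts) a character matrix, optionally replays a recoding
#' ledger, searches for the most-parsimonious trees, collapses and counts
#' them, computes ensemble CI/RI, Bremer and (optionally) bootstrap
#' supports, maps synapomorphies, and assembles everything into a
#' reproducible report.  With `out_dir` set, Newick, TSV and JSON
#' artifacts are written.
#'
#' @param x a [char_matrix()], or a path to (or text of) a NEXUS/TNT
#'   matrix
#' @param config an [analysis_config()]
#' @param format input format when `x` is a file
#' @param out_dir optional output directory for artifact files
#' @return a list of class `analysis_report`; main fields: `L_min`,
#'   `mpt_count`, `CI`, `RI`, `trees`, `consensus`, `supports`,
#'   `apomorphies`, `bootstrap`, `stats`, `settings`
#' @examples
#' sim <- simulate_matrix(n_taxa = 7, n_char = 30, seed = 11)
#' rep <- run_analysis(sim$matrix,
#'                     analysis_config(replicates = 5, bremer = FALSE,
#'                                     outgroup = "t1"))
#' rep
#' @export
run_analysis <- function(x, config = analysis_config(),
                         format = "auto", out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  m <- stage("read", read_matrix_auto(x, format))
  if (!is.null(config$recodings)) {
    led <- if (inherits(config$recodings, "recoding_ledger")) config$recodings
           else read_recoding_ledger(config$recodings)
    m <- stage("recode", apply_recodings(m, led))
  }
  if (isTRUE(config$ordered_all)) m <- set_ordered(m, TRUE)

  sr <- stage("search", mp_search(m, config$method,
                                  replicates = config$replicates,
                                  hold = config$hold, seed = config$seed,
                                  max_trees = config$max_trees))
  trees <- sr$trees
  collapsed <- if (isTRUE(config$collapse)) {
    stage("collapse", {
      cl <- lapply(trees, collapse_zero_branches, m = m)
      keys <- vapply(cl, phylo_topology_key, character(1),
                     taxa = sort(m$taxa))
      cl[!duplicated(keys)]
    })
  } else trees
  cons <- stage("consensus", strict_consensus(trees))
  stats <- stage("stats", ensemble_stats(m, trees[[1]],
                                         config$ci_include_uninformative))

  supports <- NULL
  if (isTRUE(config$bremer)) {
    supports <- stage("bremer", bremer_supports(
      m, sr, seed = config$seed + 1L, cap = config$bremer_cap))
  }
  boot <- NULL
  if (isTRUE(config$bootstrap)) {
    boot <- stage("bootstrap", bootstrap_supports(
      m, replicates = config$bootstrap_reps, seed = config$seed + 2L,
      search_replicates = config$bootstrap_search_replicates,
      hold = config$hold))
    if (!is.null(supports)) {
      supports$bootstrap <- boot$table$bootstrap[
        match(supports$clade, boot$table$clade)]
    }
  }
  apo <- NULL
  if (isTRUE(config$apomorphies)) {
    apo <- stage("apomorphies",
                 synapomorphy_map(trees[[1]], m, outgroup = config$outgroup))
  }

  report <- structure(list(
    L_min = sr$length,
    mpt_count = length(collapsed),
    mpt_count_binary = length(trees),
    CI = stats$CI, RI = stats$RI,
    trees = trees, collapsed_trees = collapsed, consensus = cons,
    stats = stats, supports = supports, bootstrap = boot,
    apomorphies = apo,
    taxa = m$taxa,
    settings = c(config[setdiff(names(config), "recodings")],
                 list(search_method = sr$method,
                      recoded = !is.null(config$recodings)))
  ), class = "analysis_report")
  if (!is.null(out_dir)) write_report_files(report, m, out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("parsimony analysis report\n")
  cat(sprintf("  best length: %g (%s search)\n", x$L_min,
              x$settings$search_method))
  cat(sprintf("  MPTs: %d (collapsed; %d binary)\n", x$mpt_count,
              x$mpt_count_binary))
  cat(sprintf("  CI = %.2f  RI = %s\n", round(x$CI, 2),
              if (is.na(x$RI)) "undefined" else sprintf("%.2f", round(x$RI, 2))))
  if (!is.null(x$supports)) {
    cat("  Bremer supports:\n")
    for (i in seq_len(nrow(x$supports)))
      cat(sprintf("    %s%s: %s\n",
                  ifelse(x$supports$censored[i], ">", ""),
                  x$supports$bremer[i], x$supports$clade[i]))
  }
  invisible(x)
}

write_report_files <- function(report, m, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  ape::write.tree(do.call(c, report$trees), p("mpts.nwk"))
  ape::write.tree(report$consensus, p("strict_consensus.nwk"))
  write.table(report$stats$per_char, p("per_char_stats.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(report$supports))
    write.table(as.data.frame(report$supports), p("supports.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(report$bootstrap)) {
    write.table(report$bootstrap$table, p("bootstrap.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    ape::write.tree(report$bootstrap$tree, p("bootstrap_majority.nwk"))
  }
  if (!is.null(report$apomorphies))
    write.table(as.data.frame(report$apomorphies), p("apomorphies.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  json <- list(L_min = report$L_min, mpt_count = report$mpt_count,
               mpt_count_binary = report$mpt_count_binary,
               CI = report$CI, RI = report$RI,
               settings = report$settings[!vapply(report$settings, is.null,
                                                  logical(1))])
  jsonlite::write_json(json, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Reproduce the published Promyliobatis analysis
#'
#' Runs the full workflow at the published settings (heuristic search
#' with 1000 random addition replicates, TBR, hold 1, all characters
#' unordered with equal weight) on the published 30-taxon, 103-character
#' pelagic-stingray matrix, which is assembled from prior studies and is
#' NOT distributed with this package; supply it as a NEXUS or TNT file.
#' The published results for comparison: a single most-parsimonious tree
#' of 211 steps, CI 0.65, RI 0.81, Bremer 9 (Myliobatiformes), 11
#' (pelagic stingrays), 1 (Gymnura + pelagic stingrays), and 16
#' synapomorphies on the pelagic-stingray stem.
#'
#' @param matrix_file path to the assembled matrix (NEXUS or TNT)
#' @param seed master seed
#' @param replicates random addition replicates (published: 1000)
#' @param apply_recodings replay [promyliobatis_recodings()] first (set
#'   if the supplied matrix predates the documented edits)
#' @param out_dir optional artifact directory
#' @return an `analysis_report`
#' @export
reproduce_published_analysis <- function(matrix_file, seed = 1L,
                                         replicates = 1000L,
                                         apply_recodings = FALSE,
                                         out_dir = NULL) {
  cfg <- analysis_config(method = "heuristic", replicates = replicates,
                         hold = 1L, seed = seed, bremer = TRUE,
                         bootstrap = TRUE,
                         recodings = if (apply_recodings)
                           promyliobatis_recodings() else NULL)
  run_analysis(matrix_file, cfg, out_dir = out_dir)
}
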