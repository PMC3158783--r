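# Configuration-driven orchestration of the whole protocol:
# encode -> loops -> words -> enrich -> classify -> coverage -> annotate.
# All output tables are TSV with 1-based inclusive residue coordinates.

.writeTSV <- function(x, file) {
  write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a run configuration
#'
#' Configurations are structured text (YAML, or JSON for `.json`
#' files) with two blocks: `input` (one of `loops`, `letters` or
#' `structures`, plus `alphabet`, `groups`, optional `annotations`) and
#' `params`.  Defaults are filled in for absent parameters; the
#' round-trip through the file format is lossless for all scalar
#' fields.
#'
#' @param file path to a YAML or JSON configuration file.
#' @return a named list with elements `input`, `params`, `output`.
#' @export
readRunConfig <- function(file) {
  cfg <- if (grepl("\\.json$", file)) jsonlite::read_json(file, simplifyVector = TRUE)
         else yaml::read_yaml(file)
  .fillConfig(cfg)
}

.defaultParams <- function() {
  list(wordLength = 4L, minCountCorpus = 5L, minCountGroup = 5L,
       markovOrder = 1L, alpha = 0.05, maxCaGap = 4.5, minOverlap = 1L,
       ubiqMinSf = 5L, extremeUbiqLp = 10, moderateLp = 10,
       extremeSpecLp = 50, functionalPrecision = 0.40, seed = 1L)
}

.fillConfig <- function(cfg) {
  p <- .defaultParams()
  for (nm in names(cfg$params)) p[[nm]] <- cfg$params[[nm]]
  stopifnot(p$wordLength >= 1L, p$alpha > 0, p$alpha < 1)
  cfg$params <- p
  cfg
}

#' Run the full motif-discovery pipeline
#'
#' Executes the protocol end to end: obtain structural-letter sequences
#' (from PDB structures plus an alphabet model, from a letter FASTA, or
#' from a ready-made loop table), extract loops and overlapping words,
#' filter rare word types, compute exact per-group over-representation,
#' summarise and categorise words, compute coverage rates of the main
#' word subsets, and — when annotations are supplied — precision and
#' functional-word calls.  Every stage's table is written to
#' `output_dir` together with a manifest recording the configuration,
#' its hash and the seed, so reruns with the same inputs and
#' configuration are reproducible.
#'
#' @param config a configuration list (see [readRunConfig()]) or a path
#'   to a configuration file.  Recognised `input` fields:
#'   \describe{
#'     \item{`structures`}{directory of PDB files (requires `alphabet`).}
#'     \item{`letters`}{letter-sequence FASTA (requires `alphabet` for
#'       letter classes).}
#'     \item{`loops`}{TSV of a ready-made loop table (statistics-only
#'       entry point).}
#'     \item{`groups`}{TSV mapping `loop_id` or `protein_id` to
#'       `group_id` (required).}
#'     \item{`annotations`}{optional annotation TSV.}
#'   }
#' @param output_dir directory for the result tables (created if
#'   needed).
#' @return invisibly, a list with all intermediate tables: `letters`,
#'   `loops`, `occurrences`, `enrichment`, `lpSig`, `summary`,
#'   `coverage`, `precision` (NULL without annotations).
#' @export
runPipeline <- function(config, output_dir = "loopmotifs_out") {
  if (is.character(config)) config <- readRunConfig(config)
  config <- .fillConfig(config)
  p <- config$params
  inp <- config$input
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  model <- NULL
  if (!is.null(inp$alphabet)) model <- readAlphabet(inp$alphabet)

  if (!is.null(inp$loops)) {
    loops <- read.delim(inp$loops, stringsAsFactors = FALSE)
    letterTab <- NULL
  } else if (!is.null(inp$letters)) {
    if (is.null(model)) stop("input 'letters' requires an 'alphabet' model file")
    letterTab <- readLetterFasta(inp$letters)
    loops <- extractLoops(letterTab, model)
  } else if (!is.null(inp$structures)) {
    if (is.null(model))
      stop("input 'structures' requires an 'alphabet' model file")
    files <- list.files(inp$structures, pattern = "\\.(pdb|ent)$",
                        full.names = TRUE)
    if (length(files) == 0L) stop("no PDB files in ", inp$structures)
    letterTab <- do.call(rbind, lapply(files, function(f) {
      traces <- readCaTraces(f)
      do.call(rbind, lapply(traces, encodeStructure, model = model,
                            maxCaGap = p$maxCaGap))
    }))
    loops <- extractLoops(letterTab, model)
  } else {
    stop("config input must provide one of 'loops', 'letters' or 'structures'")
  }
  if (is.null(inp$groups)) stop("config input lacks the 'groups' table")
  groupsTab <- read.delim(inp$groups, stringsAsFactors = FALSE)
  if (nrow(groupsTab) == 0L) stop("empty group table: ", inp$groups)
  if (!"loop_id" %in% names(groupsTab)) {
    if (!"protein_id" %in% names(groupsTab))
      stop("groups table needs a 'loop_id' or 'protein_id' column")
    groupsTab <- data.frame(
      loop_id = loops$loop_id,
      group_id = groupsTab$group_id[match(loops$protein_id,
                                          groupsTab$protein_id)])
    groupsTab <- groupsTab[!is.na(groupsTab$group_id), , drop = FALSE]
  }
  loops <- loops[loops$loop_id %in% groupsTab$loop_id, , drop = FALSE]
  if (nrow(loops) == 0L) stop("no loops remain after group assignment")

  occ <- filterWords(extractWords(loops, L = p$wordLength),
                     min_count = p$minCountCorpus)
  enr <- enrichWords(loops, groupsTab, order = p$markovOrder,
                     minCountGroup = p$minCountGroup,
                     minCountCorpus = p$minCountCorpus,
                     wordLength = p$wordLength)
  lpSig <- bonferroniThreshold(p$alpha, max(1L, sum(enr$tested)))
  thr <- wordThresholds(lpSig, ubiqMinSf = p$ubiqMinSf,
                        extremeUbiqLp = p$extremeUbiqLp,
                        moderateLp = p$moderateLp,
                        extremeSpecLp = p$extremeSpecLp,
                        functionalPrecision = p$functionalPrecision)
  summ <- categorizeWords(summarizeWords(enr, lpSig), thr)

  subsets <- list(
    over_represented = summ$word[summ$category != "not_over_represented"],
    extreme_ubiquitous = summ$word[summ$category == "extreme_ubiquitous"],
    extreme_superfamily_specific =
      summ$word[summ$category == "extreme_superfamily_specific"])
  coverage <- do.call(rbind, lapply(names(subsets), function(nm) {
    cv <- coverageRates(intersect(subsets[[nm]], occ$word), occ, loops)
    data.frame(subset = nm, n_words = length(subsets[[nm]]), t(cv))
  }))

  prec <- NULL
  if (!is.null(inp$annotations)) {
    anno <- readAnnotations(inp$annotations)
    prec <- precisionTable(occ, anno, minOverlap = p$minOverlap)
    summ <- callFunctionalWords(summ, prec,
                                thrPrecision = p$functionalPrecision)
  }

  if (!is.null(letterTab)) .writeTSV(letterTab, file.path(output_dir, "letters.tsv"))
  .writeTSV(loops, file.path(output_dir, "loops.tsv"))
  .writeTSV(occ, file.path(output_dir, "words.tsv"))
  .writeTSV(enr, file.path(output_dir, "enrichment.tsv"))
  .writeTSV(summ, file.path(output_dir, "summary.tsv"))
  .writeTSV(coverage, file.path(output_dir, "coverage.tsv"))
  if (!is.null(prec)) .writeTSV(prec, file.path(output_dir, "precision.tsv"))

  cfgNoOut <- config[c("input", "params")]
  cfgJson <- jsonlite::toJSON(cfgNoOut, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(cfgJson, tmp)
  manifest <- list(config = cfgNoOut,
                   config_hash = unname(tools::md5sum(tmp)),
                   seed = p$seed, lp_sig = lpSig,
                   n_loops = nrow(loops), n_tested = sum(enr$tested),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(letters = letterTab, loops = loops, occurrences = occ,
                 enrichment = enr, lpSig = lpSig, summary = summ,
                 coverage = coverage, precision = prec))
}
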