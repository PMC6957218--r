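#' Scan one structure for the minimal Rossmann-like motif
#'
#' Convenience composition: secondary-structure assignment, interaction
#' matrix, motif matching and (optionally) domain anchoring.
#'
#' @param s a \linkS4class{ProteinStructure} or path to a PDB-format file.
#' @param domains optional data.frame (\code{id}, \code{range}) of domain
#'   ranges to anchor matches to.
#' @param hbond_cutoff,contact_cutoff,t_angle_min geometry thresholds passed
#'   to \code{\link{buildInteractionMatrix}}.
#' @return list with \code{structure}, \code{sse}, \code{matrix} and
#'   \code{matches}.
#' @export
scanStructure <- function(s, domains = NULL, hbond_cutoff = 3.5,
                          contact_cutoff = 6.5, t_angle_min = 30) {
  if (is.character(s)) s <- readStructure(s)
  sse <- assignSSE(s)
  im <- buildInteractionMatrix(sse, s, hbond_cutoff = hbond_cutoff,
                               contact_cutoff = contact_cutoff,
                               t_angle_min = t_angle_min)
  matches <- matchRLM(im, s)
  if (!is.null(domains) && length(matches))
    matches <- assignToDomain(matches, domains)
  list(structure = s, sse = sse, matrix = im, matches = matches)
}

#' Run the full detection and annotation pipeline
#'
#' Orchestrates motif scanning over a set of coordinate files and, when the
#' corresponding annotation tables are supplied, family categorisation,
#' pathway enrichment, cofactor summaries and ligand contacts. Per-structure
#' failures are logged and skipped (fail-soft); the returned status is
#' non-zero when any stage failed.
#'
#' @param config named list:
#'   \describe{
#'     \item{pdb}{character vector of PDB-format files, or one directory.}
#'     \item{out}{output directory for TSV reports (optional).}
#'     \item{domains}{data.frame or TSV path with columns structure, id,
#'       range (optional).}
#'     \item{ec}{data.frame or TSV path: structure, ec (optional).}
#'     \item{fgroups}{data.frame or TSV path: structure, fgroup (optional).}
#'     \item{pathways, membership}{pathway tables (optional): pathway/class/
#'       major_group and pathway/ec.}
#'     \item{cofactors}{data.frame or TSV path: ec, cofactor (optional).}
#'     \item{contact_cutoff, hbond_cutoff, t_angle_min}{geometry thresholds
#'       (defaults 4.0 / 3.5 / 30).}
#'     \item{ligand_cutoff}{ligand contact cutoff (default 4.0).}
#'   }
#' @return list with \code{rlm} (match table), \code{contacts},
#'   \code{fgroup_records}, \code{enrichment}, \code{cofactors},
#'   \code{failures} (data.frame of structure/stage/error) and
#'   \code{status} (0 = clean).
#' @export
runPipeline <- function(config) {
  cfg <- config
  get_tab <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) utils::read.delim(x, stringsAsFactors = FALSE) else x
  }
  files <- cfg$pdb
  if (length(files) == 1L && dir.exists(files))
    files <- list.files(files, pattern = "\\.(pdb|ent)$", full.names = TRUE)
  failures <- list()
  fail <- function(id, stage, e) {
    message("pipeline failure [", stage, "] ", id, ": ", conditionMessage(e))
    failures[[length(failures) + 1L]] <<- data.frame(
      structure = id, stage = stage, error = conditionMessage(e),
      stringsAsFactors = FALSE)
  }
  domains <- get_tab(cfg$domains)
  rlm_rows <- list(); contact_rows <- list()
  for (f in sort(files)) {
    id <- sub("\\.[^.]*$", "", basename(f))
    scan <- tryCatch({
      s <- readStructure(f)
      dom <- if (!is.null(domains))
        domains[domains$structure == s@id, c("id", "range"), drop = FALSE]
      else NULL
      if (!is.null(dom) && nrow(dom) == 0L) dom <- NULL
      scanStructure(s, domains = dom,
                    hbond_cutoff = cfg$hbond_cutoff %||% 3.5,
                    contact_cutoff = cfg$contact_cutoff %||% 6.5,
                    t_angle_min = cfg$t_angle_min %||% 30)
    }, error = function(e) { fail(id, "scan", e); NULL })
    if (is.null(scan)) next
    if (length(scan$matches)) {
      rlm_rows[[length(rlm_rows) + 1L]] <- matchTable(scan$matches)
      ct <- tryCatch(
        findContacts(scan$structure, match = scan$matches[[1]],
                     cutoff = cfg$ligand_cutoff %||% 4.0),
        error = function(e) { fail(id, "contacts", e); NULL })
      if (!is.null(ct) && nrow(ct))
        contact_rows[[length(contact_rows) + 1L]] <- ct
    }
  }
  rlm <- if (length(rlm_rows)) do.call(rbind, rlm_rows) else
    matchTable(list())
  contacts <- if (length(contact_rows)) do.call(rbind, contact_rows) else NULL

  fgr <- NULL; enr <- NULL; cof <- NULL
  ec_tab <- get_tab(cfg$ec); fg_tab <- get_tab(cfg$fgroups)
  if (!is.null(ec_tab) && !is.null(fg_tab))
    fgr <- tryCatch(buildFGroupRecords(fg_tab, ec_tab),
                    error = function(e) { fail("-", "fgroups", e); NULL })
  pw <- get_tab(cfg$pathways); memb <- get_tab(cfg$membership)
  if (!is.null(pw) && !is.null(memb) && !is.null(ec_tab) &&
      "rlm" %in% names(ec_tab)) {
    enr <- tryCatch({
      cc <- pathwayClassCounts(list(ec = ec_tab, pathways = pw,
                                    membership = memb))
      enrichmentTable(cc$class_counts, cc$group_rlm, cc$group_all)
    }, error = function(e) { fail("-", "enrichment", e); NULL })
  }
  cof_tab <- get_tab(cfg$cofactors)
  if (!is.null(cof_tab))
    cof <- tryCatch(cofactorJoin(cof_tab, get_tab(cfg$ec_fgroup)),
                    error = function(e) { fail("-", "cofactors", e); NULL })

  if (!is.null(cfg$out)) {
    dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, nm) if (!is.null(x) && NROW(x))
      utils::write.table(x, file.path(cfg$out, nm), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    wt(rlm, "rlm_matches.tsv")
    wt(contacts, "ligand_contacts.tsv")
    if (!is.null(fgr))
      wt(fgr[, setdiff(names(fgr), "ecs")], "fgroup_categories.tsv")
    wt(enr, "enrichment.tsv")
    if (!is.null(cof)) {
      wt(cof$summary, "cofactor_summary.tsv")
      wt(cof$class_breakdown, "cofactor_classes.tsv")
    }
    if (length(failures))
      wt(do.call(rbind, failures), "failures.tsv")
  }
  list(rlm = rlm, contacts = contacts, fgroup_records = fgr,
       enrichment = enr, cofactors = cof,
       failures = if (length(failures)) do.call(rbind, failures) else NULL,
       status = if (length(failures)) 1L else 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
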