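#' Construct / load a ligand-receptor pair database
#'
#' @param pairs `data.frame` with columns `ligand` and `receptor`.
#' @param source Free-text source tag.
#' @return An `lr_database`: list with `pairs` (deduplicated,
#'   case-normalized to upper) and `source`.
#' @export
lr_database <- function(pairs, source = "user") {
  if (!all(c("ligand", "receptor") %in% names(pairs)))
    stop("pair table needs columns 'ligand' and 'receptor'", call. = FALSE)
  pairs <- data.frame(ligand = toupper(trimws(pairs$ligand)),
                      receptor = toupper(trimws(pairs$receptor)),
                      stringsAsFactors = FALSE)
  if (any(!nzchar(pairs$ligand)) || any(!nzchar(pairs$receptor)))
    stop("empty gene name in pair table", call. = FALSE)
  pairs <- unique(pairs)
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, source = source), class = "lr_database")
}

#' @export
print.lr_database <- function(x, ...) {
  cat("<lr_database> ", nrow(x$pairs), " unique ligand-receptor pairs (",
      x$source, ")\n", sep = "")
  invisible(x)
}

#' Load a ligand-receptor database from TSV
#'
#' @param path TSV with header columns `ligand`, `receptor`.
#' @return An [lr_database()].
#' @export
load_lr_database <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% names(tab)))
    stop("database TSV must have columns 'ligand' and 'receptor'",
         call. = FALSE)
  lr_database(tab, source = basename(path))
}

#' Infer directional ligand-receptor crosstalk edges
#'
#' Retains each database pair whose ligand is expressed by the sender above
#' `fpkm_min` FPKM and whose receptor is expressed by the receiver above
#' `counts_min` read counts. Both thresholds are strict: a ligand at exactly
#' 0.05 FPKM or a receptor at exactly 10 counts is excluded. Pairs with
#' either gene absent from its profile are dropped and tallied.
#'
#' @param sender Named numeric vector: ligand-side expression in FPKM.
#' @param receiver Named numeric vector: receptor-side expression in read
#'   counts.
#' @param db An [lr_database()].
#' @param fpkm_min Strict lower threshold on ligand FPKM (default 0.05).
#' @param counts_min Strict lower threshold on receptor counts (default 10).
#' @param direction Length-2 character `(sender label, receiver label)`.
#' @return `data.frame` of edges (`ligand`, `receptor`, `direction`,
#'   `ligand_fpkm`, `receptor_counts`); attribute `"dropped_pairs"` counts
#'   database pairs with a gene missing from a profile.
#' @export
infer_crosstalk <- function(sender, receiver, db, fpkm_min = 0.05,
                            counts_min = 10,
                            direction = c("sender", "receiver")) {
  stopifnot(inherits(db, "lr_database"))
  if (!length(sender) || !length(receiver))
    stop("empty expression profile", call. = FALSE)
  lig <- db$pairs$ligand
  rec <- db$pairs$receptor
  lf <- unname(sender[lig])
  rc <- unname(receiver[rec])
  dropped <- is.na(lf) | is.na(rc)
  pass <- !dropped & lf > fpkm_min & rc > counts_min
  out <- data.frame(ligand = lig[pass], receptor = rec[pass],
                    direction = rep(paste(direction[1], direction[2],
                                          sep = "->"), sum(pass)),
                    ligand_fpkm = lf[pass], receptor_counts = rc[pass],
                    stringsAsFactors = FALSE)
  out <- out[order(out$ligand, out$receptor), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_pairs") <- sum(dropped)
  out
}

#' Bidirectional crosstalk maps between two profiles
#'
#' Applies [infer_crosstalk()] in both directions with the same thresholds:
#' A's ligands (FPKM layer) against B's receptors (count layer), and the
#' converse.
#'
#' @param profileA,profileB Each a list with named numeric elements `fpkm`
#'   and `counts`.
#' @param db An [lr_database()].
#' @param labels Length-2 character vector of profile labels
#'   (default `c("A", "B")`).
#' @param fpkm_min,counts_min Thresholds passed to [infer_crosstalk()].
#' @return List with edge tables `ab` (A -> B) and `ba` (B -> A).
#' @export
bidirectional_maps <- function(profileA, profileB, db,
                               labels = c("A", "B"),
                               fpkm_min = 0.05, counts_min = 10) {
  for (p in list(profileA, profileB)) {
    if (!all(c("fpkm", "counts") %in% names(p)))
      stop("profiles need both an 'fpkm' and a 'counts' layer",
           call. = FALSE)
  }
  list(
    ab = infer_crosstalk(profileA$fpkm, profileB$counts, db,
                         fpkm_min, counts_min, direction = labels),
    ba = infer_crosstalk(profileB$fpkm, profileA$counts, db,
                         fpkm_min, counts_min, direction = rev(labels)))
}
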