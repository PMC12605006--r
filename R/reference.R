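# Crystal-reference handling: fetch the agonist-bound active-state LBD
# structure, verify its author numbering against the expected threonines,
# and measure the reference C-beta pair distance that defines the distance
# criterion cutoff.

#' Fetch a PDB entry from RCSB
#'
#' Downloads `<id>.pdb` into `dest_dir` (skipped if already present).
#' Requires network access; analysis functions accept any local PDB path, so
#' offline runs can supply a pre-downloaded or surrogate file instead.
#'
#' @param id 4-character PDB identifier (e.g. `"6HL1"`)
#' @param dest_dir download directory
#' @param quiet suppress download progress
#' @return path to the downloaded file
#' @export
fetch_pdb <- function(id, dest_dir = tempdir(), quiet = TRUE) {
  stopifnot(grepl("^[0-9][A-Za-z0-9]{3}$", id))
  dest <- file.path(dest_dir, paste0(toupper(id), ".pdb"))
  if (file.exists(dest)) return(dest)
  url <- sprintf("https://files.rcsb.org/download/%s.pdb", toupper(id))
  status <- tryCatch(utils::download.file(url, dest, quiet = quiet, mode = "wb"),
                     error = function(e) -1L, warning = function(w) -1L)
  if (!identical(status, 0L) || !file.exists(dest) || file.size(dest) == 0) {
    unlink(dest)
    stop("could not download PDB entry ", id, " from ", url, call. = FALSE)
  }
  dest
}

#' Verify numbering and measure the reference C-beta pair distance
#'
#' Before measuring, checks that the residues labelled `res_a` and `res_b`
#' in the file's author numbering have the expected residue types (both
#' threonine for the 296/466 pair) — the deposited entry's numbering is not
#' guaranteed to match the UniProt frame, so this guards against a shifted
#' register. Then returns the C-beta pair distance in the first chain (or a
#' given chain).
#'
#' @param model an `h12_structure` (e.g. from [read_pdb()])
#' @param res_a,res_b residue numbers (author numbering)
#' @param expect_resname expected 3-letter residue code at both sites
#'   (`NULL` skips the check)
#' @param chain chain to measure in; default: first chain containing both
#'   residues
#' @return distance in Angstrom
#' @export
reference_cbeta_distance <- function(model, res_a = 296, res_b = 466,
                                     expect_resname = "THR", chain = NULL) {
  stopifnot(inherits(model, "h12_structure"))
  a <- model$atoms
  if (is.null(chain)) {
    chains <- unique(a$chain)
    has_both <- vapply(chains, function(ch) {
      all(c(res_a, res_b) %in% a$resno[a$chain == ch])
    }, logical(1))
    if (!any(has_both)) {
      stop(sprintf("no chain contains both residues %d and %d", res_a, res_b),
           call. = FALSE)
    }
    chain <- chains[which(has_both)[1]]
  }
  if (!is.null(expect_resname)) {
    for (rn in c(res_a, res_b)) {
      types <- unique(a$resname[a$chain == chain & a$resno == rn])
      if (!identical(types, expect_resname)) {
        stop(sprintf(
          "numbering check failed: residue %d in chain %s is %s, expected %s",
          rn, chain, paste(types, collapse = "/"), expect_resname),
          call. = FALSE)
      }
    }
  }
  xyz <- coords(model)
  ia <- select_atoms(model, selection_spec(c(res_a, res_a), "CB", chain))
  ib <- select_atoms(model, selection_spec(c(res_b, res_b), "CB", chain))
  pair_distance(xyz, ia[1], ib[1])
}
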