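# ---- StructureModel -------------------------------------------------------

#' Construct a structure model
#'
#' A structure model is an ordered atom table with chain identity, author
#' residue numbering, residue/atom names, element symbols and Cartesian
#' coordinates in Angstrom. Author numbering is authoritative throughout the
#' package: residue labels such as 296 or 466-473 refer to this numbering and
#' are never remapped on input.
#'
#' @param atoms data.frame with columns `chain` (character), `resno`
#'   (integer, 1-based author numbering), `resname` (3-letter code), `atom`
#'   (PDB atom name), `element` (symbol), `x`, `y`, `z` (Angstrom).
#' @return An object of class `h12_structure`.
#' @export
structure_model <- function(atoms) {
  required <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  if (!is.data.frame(atoms) || !all(required %in% names(atoms))) {
    stop("atoms must be a data.frame with columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  atoms <- atoms[, required]
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(atoms) == 0L) stop("structure model must contain at least one atom",
                              call. = FALSE)
  if (!all(is.finite(coords))) stop("atom coordinates must be finite",
                                    call. = FALSE)
  key <- paste(atoms$chain, atoms$resno, atoms$atom, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue, atom) identity: ",
         key[duplicated(key)][1L], call. = FALSE)
  }
  structure(list(atoms = atoms), class = "h12_structure")
}

#' @export
print.h12_structure <- function(x, ...) {
  cat(sprintf("<h12_structure: %d atoms, %d residues, chains %s>\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno))),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Coordinate matrix of a structure model
#' @param model an `h12_structure`
#' @return N x 3 numeric matrix (Angstrom)
#' @export
coords <- function(model) {
  stopifnot(inherits(model, "h12_structure"))
  as.matrix(model$atoms[, c("x", "y", "z")])
}

# ---- PDB reading ----------------------------------------------------------

# Parse one ATOM/HETATM line. Fixed-column PDB layout is tried first; a
# whitespace-tokenized fallback accepts loosely formatted records
# (serial name resname chain resno x y z).
parse_atom_line <- function(line, lineno) {
  n <- nchar(line)
  fixed_ok <- n >= 54
  if (fixed_ok) {
    xs <- substr(line, 31, 38); ys <- substr(line, 39, 46)
    zs <- substr(line, 47, 54)
    x <- suppressWarnings(as.numeric(xs))
    y <- suppressWarnings(as.numeric(ys))
    z <- suppressWarnings(as.numeric(zs))
    fixed_ok <- !anyNA(c(x, y, z))
  }
  if (fixed_ok) {
    el <- if (n >= 78) trimws(substr(line, 77, 78)) else ""
    atom_name <- trimws(substr(line, 13, 16))
    if (el == "") el <- substr(gsub("[^A-Za-z]", "", atom_name), 1, 1)
    return(list(
      chain = trimws(substr(line, 22, 22)),
      resno = suppressWarnings(as.integer(trimws(substr(line, 23, 26)))),
      resname = trimws(substr(line, 18, 20)),
      atom = atom_name,
      element = el,
      x = x, y = y, z = z))
  }
  tok <- strsplit(trimws(line), "\\s+")[[1]]
  # record serial name resname chain resno x y z
  if (length(tok) >= 9) {
    x <- suppressWarnings(as.numeric(tok[7]))
    y <- suppressWarnings(as.numeric(tok[8]))
    z <- suppressWarnings(as.numeric(tok[9]))
    resno <- suppressWarnings(as.integer(tok[6]))
    if (!anyNA(c(x, y, z)) && !is.na(resno)) {
      return(list(chain = tok[5], resno = resno, resname = tok[4],
                  atom = tok[3],
                  element = substr(gsub("[^A-Za-z]", "", tok[3]), 1, 1),
                  x = x, y = y, z = z))
    }
  }
  stop(sprintf("malformed ATOM/HETATM coordinate fields at line %d: '%s'",
               lineno, line), call. = FALSE)
}

#' Read a PDB file
#'
#' Reads ATOM/HETATM records. Multi-model files (MODEL/ENDMDL blocks) yield
#' one model per block; all models must share atom count and ordering.
#' Author residue numbering and atom order are preserved.
#'
#' @param path path to a PDB file
#' @param multi if `TRUE` always return a list of models; by default a file
#'   without MODEL records returns a single `h12_structure`.
#' @return An `h12_structure`, or a list of them for multi-model files.
#' @export
read_pdb <- function(path, multi = NA) {
  if (!file.exists(path)) stop("PDB file does not exist: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  models <- list()
  cur <- list()
  saw_model_kw <- FALSE
  flush <- function(models, cur) {
    if (length(cur)) models[[length(models) + 1L]] <- cur
    models
  }
  for (i in seq_along(lines)) {
    rec <- substr(lines[[i]], 1, 6)
    if (startsWith(rec, "MODEL")) {
      saw_model_kw <- TRUE
      models <- flush(models, cur); cur <- list()
    } else if (startsWith(rec, "ENDMDL")) {
      models <- flush(models, cur); cur <- list()
    } else if (startsWith(rec, "ATOM") || startsWith(rec, "HETATM")) {
      cur[[length(cur) + 1L]] <- parse_atom_line(lines[[i]], i)
    }
  }
  models <- flush(models, cur)
  if (length(models) == 0L) {
    stop("no ATOM/HETATM records found in ", path, call. = FALSE)
  }
  to_model <- function(recs) {
    df <- do.call(rbind.data.frame, c(recs, list(stringsAsFactors = FALSE)))
    structure_model(df)
  }
  out <- lapply(models, to_model)
  n_atoms <- vapply(out, function(m) nrow(m$atoms), integer(1))
  if (length(unique(n_atoms)) > 1L) {
    stop("inconsistent atom count across MODEL blocks: ",
         paste(unique(n_atoms), collapse = " vs "), call. = FALSE)
  }
  if (length(out) > 1L) {
    id1 <- with(out[[1]]$atoms, paste(chain, resno, atom))
    for (k in seq_along(out)[-1]) {
      idk <- with(out[[k]]$atoms, paste(chain, resno, atom))
      if (!identical(id1, idk)) {
        stop("atom ordering differs between MODEL 1 and MODEL ", k,
             call. = FALSE)
      }
    }
  }
  if (isTRUE(multi) || (is.na(multi) && (length(out) > 1L || saw_model_kw))) {
    out
  } else {
    out[[1]]
  }
}

#' Write a structure model (or list of models) as PDB
#'
#' Coordinates are written with 3 decimals (the format's precision).
#'
#' @param model an `h12_structure` or list of them (multi-model output)
#' @param path output file path
#' @export
write_pdb <- function(model, path) {
  models <- if (inherits(model, "h12_structure")) list(model) else model
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(models) > 1L
  for (k in seq_along(models)) {
    a <- models[[k]]$atoms
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    nm <- ifelse(nchar(a$atom) < 4, paste0(" ", a$atom), a$atom)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)) %% 100000L, nm, a$resname, a$chain, a$resno,
      a$x, a$y, a$z, 1, 0, a$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---- Trajectory -----------------------------------------------------------

#' Construct a trajectory
#'
#' @param topology `h12_structure` giving atom identity and ordering
#' @param frames numeric array `n_atoms x 3 x n_frames` (Angstrom)
#' @param frame_interval_ns time between frames in nanoseconds (metadata; XYZ
#'   streams carry no time, so this is supplied, default 1 ns)
#' @param system_label free-text system label (e.g. `"inactive_WT"`)
#' @param replica_index integer replica number (>= 1)
#' @return An object of class `h12_trajectory`.
#' @export
trajectory <- function(topology, frames, frame_interval_ns = 1,
                       system_label = "system", replica_index = 1L) {
  stopifnot(inherits(topology, "h12_structure"))
  if (length(dim(frames)) != 3L) stop("frames must be an n_atoms x 3 x n_frames array",
                                      call. = FALSE)
  if (dim(frames)[1] != nrow(topology$atoms) || dim(frames)[2] != 3L) {
    stop(sprintf("frame dimensions %dx%d do not match topology (%d atoms)",
                 dim(frames)[1], dim(frames)[2], nrow(topology$atoms)),
         call. = FALSE)
  }
  if (dim(frames)[3] < 1L) stop("trajectory needs at least one frame", call. = FALSE)
  if (!is.numeric(frame_interval_ns) || frame_interval_ns <= 0) {
    stop("frame_interval_ns must be a positive number", call. = FALSE)
  }
  structure(list(topology = topology, frames = frames,
                 frame_interval_ns = frame_interval_ns,
                 system_label = system_label,
                 replica_index = as.integer(replica_index)),
            class = "h12_trajectory")
}

#' @export
print.h12_trajectory <- function(x, ...) {
  cat(sprintf("<h12_trajectory: %s replica %d, %d frames x %d atoms, dt = %g ns>\n",
              x$system_label, x$replica_index, n_frames(x),
              dim(x$frames)[1], x$frame_interval_ns))
  invisible(x)
}

#' @rdname trajectory
#' @param traj an `h12_trajectory`
#' @export
n_frames <- function(traj) dim(traj$frames)[3]

#' Read a trajectory from an XYZ or multi-model PDB file
#'
#' XYZ frame blocks are: atom-count line, comment line, then
#' `element x y z` per atom. Every frame must have the topology's atom count.
#'
#' @param path trajectory file (`.xyz` or `.pdb`)
#' @param topology `h12_structure` defining atom identity/ordering
#' @inheritParams trajectory
#' @return An `h12_trajectory`.
#' @export
read_traj <- function(path, topology, frame_interval_ns = 1,
                      system_label = "system", replica_index = 1L) {
  if (!file.exists(path)) stop("trajectory file does not exist: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  n_atoms <- nrow(topology$atoms)
  if (ext == "pdb") {
    models <- read_pdb(path, multi = TRUE)
    if (nrow(models[[1]]$atoms) != n_atoms) {
      stop(sprintf("atom count mismatch at frame 1: file has %d, topology has %d",
                   nrow(models[[1]]$atoms), n_atoms), call. = FALSE)
    }
    arr <- array(NA_real_, c(n_atoms, 3L, length(models)))
    for (k in seq_along(models)) arr[, , k] <- coords(models[[k]])
  } else {
    lines <- readLines(path, warn = FALSE)
    arr_list <- list()
    i <- 1L; frame <- 0L
    while (i <= length(lines)) {
      if (!nzchar(trimws(lines[[i]]))) { i <- i + 1L; next }
      frame <- frame + 1L
      cnt <- suppressWarnings(as.integer(trimws(lines[[i]])))
      if (is.na(cnt)) stop(sprintf("bad atom-count line at frame %d (line %d)",
                                   frame, i), call. = FALSE)
      if (cnt != n_atoms) {
        stop(sprintf("atom count mismatch at frame %d: file has %d, topology has %d",
                     frame, cnt, n_atoms), call. = FALSE)
      }
      if (i + 1L + cnt > length(lines)) {
        stop(sprintf("truncated frame %d: expected %d atom lines", frame, cnt),
             call. = FALSE)
      }
      block <- lines[(i + 2L):(i + 1L + cnt)]
      m <- matrix(NA_real_, cnt, 3L)
      toks <- strsplit(trimws(block), "\\s+")
      for (j in seq_len(cnt)) {
        tk <- toks[[j]]
        if (length(tk) < 4L) stop(sprintf("malformed atom line in frame %d, atom %d",
                                          frame, j), call. = FALSE)
        v <- suppressWarnings(as.numeric(tk[2:4]))
        if (anyNA(v)) stop(sprintf("non-numeric coordinates in frame %d, atom %d",
                                   frame, j), call. = FALSE)
        m[j, ] <- v
      }
      arr_list[[frame]] <- m
      i <- i + 2L + cnt
    }
    if (frame == 0L) stop("no frames found in ", path, call. = FALSE)
    arr <- array(NA_real_, c(n_atoms, 3L, frame))
    for (k in seq_len(frame)) arr[, , k] <- arr_list[[k]]
  }
  trajectory(topology, arr, frame_interval_ns, system_label, replica_index)
}

#' Write a trajectory as an XYZ frame stream
#'
#' @param traj an `h12_trajectory`
#' @param path output `.xyz` path
#' @export
write_traj_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "h12_trajectory"))
  el <- traj$topology$atoms$element
  el[!nzchar(el)] <- "X"
  con <- file(path, "w")
  on.exit(close(con))
  nat <- dim(traj$frames)[1]
  for (k in seq_len(n_frames(traj))) {
    writeLines(as.character(nat), con)
    writeLines(sprintf("frame %d t= %.6f ns %s rep %d", k,
                       (k - 1) * traj$frame_interval_ns,
                       traj$system_label, traj$replica_index), con)
    f <- traj$frames[, , k, drop = TRUE]
    writeLines(sprintf("%-2s %12.3f %12.3f %12.3f", el,
                       f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(path)
}

# ---- Atom selection -------------------------------------------------------

#' Selection specification
#'
#' @param residue_range inclusive `c(start, end)` in author numbering
#' @param atom_names character vector of PDB atom names, e.g. `"CB"`
#' @param chain optional chain identifier; `NULL` matches any chain
#' @return An object of class `h12_selection`.
#' @export
selection_spec <- function(residue_range, atom_names, chain = NULL) {
  stopifnot(length(residue_range) == 2L, residue_range[1] <= residue_range[2])
  structure(list(residue_range = as.integer(residue_range),
                 atom_names = as.character(atom_names), chain = chain),
            class = "h12_selection")
}

#' @export
format.h12_selection <- function(x, ...) {
  sprintf("residues %d-%d, atoms {%s}%s", x$residue_range[1],
          x$residue_range[2], paste(x$atom_names, collapse = ","),
          if (is.null(x$chain)) "" else paste0(", chain ", x$chain))
}

#' Resolve an atom selection against a structure model
#'
#' Returns the ordered indices (sorted by chain, residue number, then file
#' order) of atoms matching the selection. An empty selection is an error:
#' both state criteria depend on single named atoms, so a missing atom (for
#' instance the C-beta of a glycine) must fail loudly rather than be skipped.
#'
#' @param model an `h12_structure`
#' @param spec an `h12_selection`
#' @return integer vector of atom indices
#' @export
select_atoms <- function(model, spec) {
  stopifnot(inherits(model, "h12_structure"), inherits(spec, "h12_selection"))
  a <- model$atoms
  keep <- a$resno >= spec$residue_range[1] & a$resno <= spec$residue_range[2] &
    a$atom %in% spec$atom_names
  if (!is.null(spec$chain)) keep <- keep & a$chain == spec$chain
  idx <- which(keep)
  if (length(idx) == 0L) {
    stop("selection matched no atoms: ", format(spec), call. = FALSE)
  }
  idx[order(a$chain[idx], a$resno[idx], idx)]
}
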