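# stable float formatting policy for all writers
.fmt <- function(x) sprintf("%.10f", x)

#' Read an XYZ file
#'
#' Standard XYZ (coordinates in Angstrom): atom count, comment, then
#' element x y z per line. Multi-frame files return a list of geometries.
#'
#' @param path file path.
#' @param multi return all frames (\code{TRUE}) or the first only.
#' @return a \code{qmmd_geometry}, or a list of them when
#'   \code{multi = TRUE}.
#' @export
read_xyz <- function(path, multi = FALSE) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty XYZ file: ", path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) {
      stop("malformed atom count header at line ", i, " of ", path)
    }
    if (i + 1L + n > length(lines)) {
      stop("truncated XYZ frame starting at line ", i, " of ", path)
    }
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    els <- vapply(rows, `[[`, character(1), 1L)
    xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    if (anyNA(xyz)) stop("non-numeric coordinate in frame at line ", i)
    frames[[length(frames) + 1L]] <- geometry(els, xyz)
    i <- i + 2L + n
    if (!multi) break
  }
  if (multi) frames else frames[[1L]]
}

#' Write geometries to an XYZ file
#'
#' @param geoms a \code{qmmd_geometry} or list of them (multi-frame).
#' @param path output path.
#' @param comments per-frame comment lines (units tag appended).
#' @return \code{path}, invisibly.
#' @export
write_xyz <- function(geoms, path, comments = NULL) {
  if (inherits(geoms, "qmmd_geometry")) geoms <- list(geoms)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(geoms)) {
    g <- geoms[[f]]
    cm <- if (is.null(comments)) sprintf("frame %d", f) else comments[[f]]
    writeLines(c(as.character(n_atoms(g)),
                 paste(cm, "[coordinates: angstrom]")), con)
    writeLines(sprintf("%-3s %s %s %s", g$elements,
                       .fmt(g$coords[, 1]), .fmt(g$coords[, 2]),
                       .fmt(g$coords[, 3])), con)
  }
  invisible(path)
}

#' Read a PDB subset (ATOM/HETATM records)
#'
#' Fixed-column parse of ATOM/HETATM records; coordinates in Angstrom.
#' Alternate locations other than the first conformer (blank or 'A') are
#' dropped with a warning.
#'
#' @param path PDB file.
#' @return a \code{qmmd_geometry} with a \code{metadata} attribute
#'   (data.frame: atom_name, residue_name, residue_seq, chain).
#' @export
read_pdb_subset <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (!length(rec)) stop("no ATOM/HETATM records in ", path)
  altloc <- substr(rec, 17, 17)
  if (any(!altloc %in% c(" ", "", "A"))) {
    warning("alternate locations present; keeping first conformer only")
    rec <- rec[altloc %in% c(" ", "", "A")]
  }
  fld <- function(a, b) trimws(substr(rec, a, b))
  name <- fld(13, 16)
  el <- fld(77, 78)
  guess <- sub("^[0-9]*", "", name)
  el <- ifelse(nzchar(el), el, substr(guess, 1, 1))
  xyz <- cbind(as.numeric(fld(31, 38)), as.numeric(fld(39, 46)),
               as.numeric(fld(47, 54)))
  if (anyNA(xyz)) stop("malformed coordinates in ", path)
  g <- geometry(el, xyz)
  attr(g, "metadata") <- data.frame(
    atom_name = name, residue_name = fld(18, 20),
    residue_seq = as.integer(fld(23, 26)), chain = fld(22, 22),
    stringsAsFactors = FALSE)
  g
}

#' Read point charges (extended-XYZ dialect)
#'
#' One charge per line: \code{x y z q} (Angstrom, elementary charges);
#' blank lines and \code{#} comments ignored. An empty file yields an
#' empty set.
#'
#' @param path file path.
#' @return a \code{qmmd_charges}.
#' @export
read_point_charges <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (!length(keep)) return(no_charges())
  rows <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(vapply(rows, length, integer(1)) != 4L |
                 vapply(rows, function(r) anyNA(suppressWarnings(
                   as.numeric(r))), logical(1)))
  if (length(bad)) {
    stop("malformed point-charge line ", keep[bad[1L]], " in ", path)
  }
  m <- t(vapply(rows, as.numeric, numeric(4)))
  point_charges(m[, 1:3, drop = FALSE], m[, 4])
}

#' Write point charges
#' @param charges a \code{qmmd_charges}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_point_charges <- function(charges, path) {
  writeLines(sprintf("%s %s %s %s",
                     .fmt(charges$positions[, 1]),
                     .fmt(charges$positions[, 2]),
                     .fmt(charges$positions[, 3]),
                     .fmt(charges$charges)), path)
  invisible(path)
}

#' Write a topology to the sectioned text format
#'
#' Sections: \code{[atoms]} (name type charge mass residue),
#' \code{[bonds]}, \code{[angles]}, \code{[dihedrals]}, \code{[lj_types]}.
#'
#' @param topology a \code{\link{topology_spec}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_topology <- function(topology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  a <- topology$atoms
  writeLines("[atoms]", con)
  writeLines(sprintf("%s %s %s %s %d", a$name, a$type, .fmt(a$charge),
                     .fmt(a$mass), a$residue), con)
  writeLines("[bonds]", con)
  b <- topology$bonds
  if (nrow(b)) writeLines(sprintf("%d %d %s %s", b$i, b$j, .fmt(b$kb),
                                  .fmt(b$r0)), con)
  writeLines("[angles]", con)
  an <- topology$angles
  if (nrow(an)) writeLines(sprintf("%d %d %d %s %s", an$i, an$j, an$k,
                                   .fmt(an$ktheta), .fmt(an$theta0)), con)
  writeLines("[dihedrals]", con)
  d <- topology$torsions
  if (nrow(d)) writeLines(sprintf("%d %d %d %d %s %d %s", d$i, d$j, d$k,
                                  d$l, .fmt(d$vn2), d$periodicity,
                                  .fmt(d$phase)), con)
  writeLines("[lj_types]", con)
  lj <- topology$lj
  if (nrow(lj)) writeLines(sprintf("%s %s %s", lj$type, .fmt(lj$eps),
                                   .fmt(lj$rmin2)), con)
  invisible(path)
}

#' Read a topology from the sectioned text format
#'
#' @param path file written by \code{\link{write_topology}} (or
#'   hand-authored in the same format).
#' @return a \code{\link{topology_spec}}.
#' @export
read_topology <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sec <- NULL
  buf <- list(atoms = list(), bonds = list(), angles = list(),
              dihedrals = list(), lj_types = list())
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      sec <- gsub("\\[|\\]", "", ln)
      if (!sec %in% names(buf)) stop("unknown topology section [", sec, "]")
    } else {
      if (is.null(sec)) stop("data before any section in ", path)
      buf[[sec]][[length(buf[[sec]]) + 1L]] <- strsplit(ln, "\\s+")[[1]]
    }
  }
  atoms <- do.call(rbind, lapply(buf$atoms, function(r) {
    data.frame(name = r[1], type = r[2], charge = as.numeric(r[3]),
               mass = as.numeric(r[4]), residue = as.integer(r[5]),
               stringsAsFactors = FALSE)
  }))
  dfor <- function(rows, cols, ints) {
    if (!length(rows)) return(NULL)
    m <- do.call(rbind, rows)
    out <- as.data.frame(m, stringsAsFactors = FALSE)
    names(out) <- cols
    for (cc in cols) {
      out[[cc]] <- if (cc %in% ints) as.integer(out[[cc]]) else
        as.numeric(out[[cc]])
    }
    out
  }
  lj <- if (length(buf$lj_types)) {
    m <- do.call(rbind, buf$lj_types)
    data.frame(type = m[, 1], eps = as.numeric(m[, 2]),
               rmin2 = as.numeric(m[, 3]), stringsAsFactors = FALSE)
  } else NULL
  topology_spec(atoms,
                dfor(buf$bonds, c("i", "j", "kb", "r0"), c("i", "j")),
                dfor(buf$angles, c("i", "j", "k", "ktheta", "theta0"),
                     c("i", "j", "k")),
                dfor(buf$dihedrals,
                     c("i", "j", "k", "l", "vn2", "periodicity", "phase"),
                     c("i", "j", "k", "l", "periodicity")),
                lj)
}

# ---------------------------------------------------------------------------

#' Read a run-configuration file (TOML-style subset)
#'
#' Sections in square brackets with \code{key = value} entries; values may
#' be numbers, booleans, quoted strings, or comma-separated arrays of
#' numbers. Known sections: scf, cas, md, qmmm, mm, metrics, global.
#' Unknown keys are rejected with their location.
#'
#' @param path config file.
#' @return nested named list of sections; defaults materialized (see
#'   \code{attr(,"effective")}).
#' @export
read_run_config <- function(path) {
  known <- list(
    global = c("seed", "output_dir"),
    scf = c("max_iterations", "energy_tolerance", "density_rmsd_tolerance",
            "diis_depth", "mode", "charge", "orthogonalizer"),
    cas = c("n_active_electrons", "n_active_orbitals", "n_states",
            "weights", "solver"),
    md = c("timestep", "n_steps", "initial_temperature", "thermostat",
           "rescale_interval", "heat_t_start", "heat_t_end",
           "heat_duration_ps", "log_interval"),
    qmmm = c("qm_atoms", "method", "basis", "state_index"),
    mm = c("cutoff", "update_interval", "restraint_radius",
           "restraint_k"),
    metrics = c("table", "reference_row"))
  lines <- readLines(path, warn = FALSE)
  sec <- "global"
  out <- stats::setNames(vector("list", length(known)), names(known))
  for (li in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[li])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[", ln)) {
      sec <- gsub("\\[|\\]", "", ln)
      if (!sec %in% names(known)) {
        stop(sprintf("unknown config section [%s] at line %d", sec, li))
      }
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop(sprintf("cannot parse line %d: '%s'", li, ln))
    key <- trimws(kv[1])
    if (!key %in% known[[sec]]) {
      stop(sprintf("unknown key '%s' in section [%s] at line %d",
                   key, sec, li))
    }
    val <- trimws(paste(kv[-1], collapse = "="))
    parsed <- if (grepl('^".*"$', val)) {
      gsub('^"|"$', "", val)
    } else if (val %in% c("true", "false")) {
      val == "true"
    } else if (grepl(",", val)) {
      as.numeric(strsplit(val, ",")[[1]])
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) val else num
    }
    out[[sec]][[key]] <- parsed
  }
  out
}

#' Write a scaling report as TSV
#'
#' @param report a \code{\link{scaling_report}} result.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_scaling_report <- function(report, path) {
  utils::write.table(format(report, digits = 10), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Command-line entry point
#'
#' Subcommands: \code{metrics --table <tsv> [--out <tsv>]},
#' \code{scf --geometry <xyz> --basis <bas|name> [--charges <xyzq>]},
#' \code{ci --geometry <xyz> --basis <bas|name> --nel <int> --norb <int>
#' [--states <int>]},
#' \code{md --geometry <xyz> --topology <top> [--config <toml>]
#' --out <prefix>},
#' \code{qmmm-md --geometry <xyz> --topology <top> --config <toml>
#' --out <prefix>}, and
#' \code{genfix --what timing|water --out <path>}. Returns an exit code
#' (0 success, 2 usage error, 1 runtime error) instead of quitting, so it
#' is testable in-process.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit code.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    message("usage: qmmd <metrics|scf|ci|md|qmmm-md|genfix> [options]\n",
            "  metrics --table timings.tsv [--out report.tsv]\n",
            "  scf --geometry mol.xyz --basis toy-minimal ",
            "[--charges charges.xyzq]\n",
            "  ci --geometry mol.xyz --basis toy-minimal --nel 2 ",
            "--norb 2 [--states 1]\n",
            "  md --geometry mol.xyz --topology mol.top ",
            "[--config run.toml] --out prefix\n",
            "  qmmm-md --geometry mol.xyz --topology mol.top ",
            "--config run.toml --out prefix\n",
            "  genfix --what timing|water --out path")
    2L
  }
  opt <- function(flag, default = NULL) {
    i <- which(argv == flag)
    if (!length(i)) return(default)
    if (i[1] == length(argv)) stop("missing value for ", flag)
    argv[i[1] + 1L]
  }
  if (!length(argv)) return(usage())
  cmd <- argv[1]
  res <- tryCatch({
    if (cmd == "metrics") {
      tab <- opt("--table")
      if (is.null(tab)) return(usage())
      rep <- scaling_report(read_timing_table(tab))
      out <- opt("--out")
      if (!is.null(out)) {
        write_scaling_report(rep, out)
        message("report written to ", out)
      } else {
        print(rep)
      }
      0L
    } else if (cmd == "scf") {
      gpath <- opt("--geometry"); bas <- opt("--basis", "toy-minimal")
      if (is.null(gpath)) return(usage())
      g <- read_xyz(gpath)
      ch <- opt("--charges")
      charges <- if (is.null(ch)) no_charges() else read_point_charges(ch)
      r <- run_rhf(g, load_basis(g, bas), charges)
      message(sprintf("RHF total energy: %.10f hartree (%s, %d iterations)",
                      r$total_energy,
                      if (r$converged) "converged" else "not converged",
                      r$iterations))
      if (r$converged) 0L else 1L
    } else if (cmd == "ci") {
      gpath <- opt("--geometry"); bas <- opt("--basis", "toy-minimal")
      nel <- opt("--nel"); norb <- opt("--norb")
      if (is.null(gpath) || is.null(nel) || is.null(norb)) return(usage())
      g <- read_xyz(gpath)
      scf <- run_rhf(g, load_basis(g, bas))
      ci <- casci(scf, cas_space(as.integer(nel), as.integer(norb)),
                  n_states = as.integer(opt("--states", "1")))
      for (s in seq_along(ci$state_energies)) {
        message(sprintf("state %d: %.10f hartree  <S^2> = %.4f", s - 1L,
                        ci$state_energies[s], ci$s2[s]))
      }
      0L
    } else if (cmd %in% c("md", "qmmm-md")) {
      gpath <- opt("--geometry"); tpath <- opt("--topology")
      outp <- opt("--out")
      if (is.null(gpath) || is.null(tpath) || is.null(outp)) {
        return(usage())
      }
      cfg <- if (!is.null(opt("--config"))) {
        read_run_config(opt("--config"))
      } else list()
      g <- read_xyz(gpath)
      topo <- read_topology(tpath)
      mdc <- md_config(
        timestep = cfg$md$timestep %||% 0.25,
        n_steps = cfg$md$n_steps %||% 100L,
        initial_temperature = cfg$md$initial_temperature %||% 0,
        thermostat = cfg$md$thermostat %||% "none",
        rescale_interval = cfg$md$rescale_interval %||% 10L,
        seed = as.integer(cfg$global$seed %||% 1L),
        log_interval = cfg$md$log_interval %||% 1L)
      nb <- nonbonded_config(cutoff = cfg$mm$cutoff %||% 12)
      backend <- if (cmd == "md") {
        mm_backend(topo, nb)
      } else {
        if (is.null(cfg$qmmm$qm_atoms)) {
          stop("qmmm-md needs qm_atoms in the [qmmm] config section")
        }
        part <- build_partition(topo, as.integer(cfg$qmmm$qm_atoms))
        qc <- qm_config(method = cfg$qmmm$method %||% "hf",
                        basis = cfg$qmmm$basis %||% "toy-minimal",
                        state_index =
                          as.integer(cfg$qmmm$state_index %||% 0L))
        qmmm_backend(g, part, qc, nb)
      }
      tr <- run_md(g$coords, g$masses, backend, mdc)
      utils::write.table(format(tr$energies, digits = 12),
                         paste0(outp, "-energies.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_xyz(lapply(tr$frames, function(f) {
        geometry(g$elements, f$positions)
      }), paste0(outp, "-trajectory.xyz"),
      comments = sprintf("t = %.4f fs", vapply(tr$frames, `[[`,
                                               numeric(1), "time_fs")))
      message("wrote ", outp, "-energies.tsv and ", outp,
              "-trajectory.xyz")
      if (tr$aborted) 1L else 0L
    } else if (cmd == "genfix") {
      what <- opt("--what"); out <- opt("--out")
      if (is.null(what) || is.null(out)) return(usage())
      if (what == "timing") {
        tt <- gen_timing_table(serial_fraction = 0.0794, t1 = 16.676,
                               core_counts = c(1, 8, 16, 32, 64, 128, 256))
        utils::write.table(tt, out, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      } else if (what == "water") {
        ws <- gen_water_sphere(radius = 6, n_waters = 10, seed = 1L)
        write_xyz(ws$geometry, out)
      } else return(usage())
      message("fixture written to ", out)
      0L
    } else {
      usage()
    }
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  res
}
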