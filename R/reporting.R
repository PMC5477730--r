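# Workflow wrappers tying the modules into the study pipeline, plus the
# thin command-line dispatcher installed under inst/cli.

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# per-OAR dose metrics in percent of prescription
.oar_metrics <- function(dose, mask, bin_width = 0.01) {
  dvh <- compute_dvh(dose, mask, bin_width)
  rx <- dose$prescription
  c(mean = 100 * mean(dose$dose[mask$occupancy]) / rx,
    d2 = 100 * dose_at_volume(dvh, 0.02) / rx,
    d50 = 100 * dose_at_volume(dvh, 0.5) / rx)
}

#' Generate phantom cases and write them to disk
#'
#' Serializes one phantom (or a cohort) into per-case directories:
#' structure and barrier masks plus both dose grids as NRRD, the paired
#' GTV meshes as binary STL, the analytic ground truth and a manifest
#' (seed and spec echo) as JSON.
#'
#' @param out_dir output directory (created if missing).
#' @param n number of cases; `n = 1` writes the spec as-is, larger `n`
#'   draws a cohort via [generate_cohort()].
#' @param spec a [phantom_spec()].
#' @param seed cohort seed (defaults to the spec's).
#' @param encoding NRRD encoding.
#' @return invisibly, the vector of case directories.
#' @export
run_generate <- function(out_dir, n = 1, spec = phantom_spec(),
                         seed = spec$seed, encoding = "gzip") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bundles <- if (n == 1) {
    spec$seed <- as.integer(seed)
    list(generate_phantom(spec))
  } else {
    generate_cohort(n, spec, seed)
  }
  dirs <- character(length(bundles))
  for (i in seq_along(bundles)) {
    b <- bundles[[i]]
    d <- file.path(out_dir, sprintf("case_%02d", i))
    dir.create(d, showWarnings = FALSE)
    for (nm in c("gtv_s", "gtv_l", "ctv_s", "ctv_l")) {
      write_nrrd(b[[nm]], file.path(d, paste0(nm, ".nrrd")), encoding)
    }
    for (nm in c("air", "bone", "anatomical")) {
      write_nrrd(b$barriers[[nm]], file.path(d, paste0("barrier_", nm, ".nrrd")),
                 encoding)
    }
    for (nm in names(b$oars)) {
      write_nrrd(b$oars[[nm]], file.path(d, paste0("oar_", nm, ".nrrd")),
                 encoding)
    }
    write_nrrd(b$dose_plan_s, file.path(d, "dose_plan_s.nrrd"), encoding)
    write_nrrd(b$dose_plan_l, file.path(d, "dose_plan_l.nrrd"), encoding)
    write_stl(mask_to_mesh(b$gtv_s), file.path(d, "gtv_s.stl"))
    write_stl(mask_to_mesh(b$gtv_l), file.path(d, "gtv_l.stl"))
    .write_json(b$ground_truth, file.path(d, "ground_truth.json"))
    dirs[i] <- d
  }
  spec_echo <- unclass(spec)
  spec_echo$iceberg_depth_solved <- .iceberg_depth(spec)
  .write_json(list(seed = as.integer(seed), n_cases = length(bundles),
                   spec = spec_echo),
              file.path(out_dir, "manifest.json"))
  invisible(dirs)
}

# resolve a geometry input to a list of S/L mesh pairs
.geometry_pairs <- function(input) {
  if (is.list(input) && all(vapply(input, inherits, logical(1), "phantom_bundle"))) {
    return(lapply(seq_along(input), function(i) {
      list(id = sprintf("case_%02d", i),
           s = mask_to_mesh(input[[i]]$gtv_s),
           l = mask_to_mesh(input[[i]]$gtv_l))
    }))
  }
  if (inherits(input, "phantom_bundle")) return(.geometry_pairs(list(input)))
  if (is.character(input) && dir.exists(input)) {
    dirs <- sort(list.dirs(input, recursive = FALSE))
    dirs <- dirs[file.exists(file.path(dirs, "gtv_s.stl"))]
    missing_l <- dirs[!file.exists(file.path(dirs, "gtv_l.stl"))]
    if (length(missing_l)) {
      stop("unpaired structures; missing L mates in: ",
           paste(basename(missing_l), collapse = ", "))
    }
    if (!length(dirs)) stop("no gtv_s.stl/gtv_l.stl pairs under ", input)
    return(lapply(dirs, function(d) {
      list(id = basename(d),
           s = read_stl(file.path(d, "gtv_s.stl")),
           l = read_stl(file.path(d, "gtv_l.stl")))
    }))
  }
  stop("run_geometry: input must be phantom bundles or a case directory")
}

#' Geometric comparison reports for paired structures
#'
#' Runs [compare_pair()] over every S/L pair found in the input (a list
#' of phantom bundles, or a directory of case subdirectories as written
#' by [run_generate()]) and summarizes the cohort.
#'
#' @param input phantom bundle(s) or a case directory.
#' @param out_dir if given, writes `geometry_reports.csv/.json` and
#'   `geometry_summary.csv` there.
#' @param sampling_density,slice_spacing passed to [compare_pair()].
#' @return list with `reports` (list of `geometry_report`) and `summary`
#'   (data frame from [summarize_cohort()]).
#' @export
run_geometry <- function(input, out_dir = NULL, sampling_density = 4,
                         slice_spacing = 2) {
  pairs <- .geometry_pairs(input)
  reports <- lapply(pairs, function(p) {
    compare_pair(p$s, p$l, sampling_density, slice_spacing, id = p$id)
  })
  summary_ <- summarize_cohort(reports)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tab <- do.call(rbind, lapply(reports, as.data.frame))
    write.csv(tab, file.path(out_dir, "geometry_reports.csv"),
              row.names = FALSE)
    .write_json(lapply(reports, unclass),
                file.path(out_dir, "geometry_reports.json"))
    write.csv(summary_, file.path(out_dir, "geometry_summary.csv"),
              row.names = FALSE)
  }
  list(reports = reports, summary = summary_)
}

# load one case directory written by run_generate into bundle-like form
.load_case <- function(d) {
  msk <- function(f) read_nrrd(file.path(d, f), as = "mask")
  oar_files <- list.files(d, pattern = "^oar_.*\\.nrrd$")
  oars <- lapply(oar_files, msk)
  names(oars) <- sub("^oar_", "", sub("\\.nrrd$", "", oar_files))
  list(ctv_s = msk("ctv_s.nrrd"), ctv_l = msk("ctv_l.nrrd"),
       dose_plan_s = read_nrrd(file.path(d, "dose_plan_s.nrrd"), as = "dose"),
       dose_plan_l = read_nrrd(file.path(d, "dose_plan_l.nrrd"), as = "dose"),
       oars = oars)
}

#' Dose and criteria evaluation of phantom plans
#'
#' For every case: extracts the CTV_L dose metrics under Plan_S (the
#' soft-tissue-window plan), evaluates plan acceptance, computes the D98%
#' of the difference volume `CTV_delta = CTV_L minus CTV_S` and its
#' under-coverage flag, and compares OAR metrics between Plan_S and
#' Plan_L.
#'
#' @param input phantom bundle(s) or a case directory written by
#'   [run_generate()].
#' @param out_dir if given, writes `evaluation.csv` and `evaluation.json`.
#' @param objectives an `objective_set`.
#' @return list with `per_case` (data frame: CTV_L metrics in percent,
#'   acceptance, CTV_delta D98% and flag, max OAR difference) and
#'   `oar_comparisons` (per-case [compare_oar_metrics()] results).
#' @export
run_evaluate <- function(input, out_dir = NULL,
                         objectives = default_objectives()) {
  cases <- if (is.character(input) && dir.exists(input)) {
    dirs <- sort(list.dirs(input, recursive = FALSE))
    dirs <- dirs[file.exists(file.path(dirs, "ctv_l.nrrd"))]
    if (!length(dirs)) stop("no cases under ", input)
    cs <- lapply(dirs, .load_case)
    names(cs) <- basename(dirs)
    cs
  } else if (inherits(input, "phantom_bundle")) {
    list(case_01 = input)
  } else {
    stats::setNames(input, sprintf("case_%02d", seq_along(input)))
  }
  rows <- list()
  oar_cmp <- list()
  for (nm in names(cases)) {
    cs <- cases[[nm]]
    delta <- mask_subtract(cs$ctv_l, cs$ctv_s)
    met <- extract_metrics(cs$dose_plan_s, cs$ctv_l,
                           target_for_hotspot = cs$ctv_l)
    verdict <- evaluate_plan(met, objectives)
    delta_d98 <- if (any(delta$occupancy)) {
      100 * dose_at_volume(compute_dvh(cs$dose_plan_s, delta), 0.98) /
        cs$dose_plan_s$prescription
    } else NA_real_
    flag <- if (is.na(delta_d98)) FALSE else {
      flag_under_coverage(delta_d98, structure_id = nm)$under_covered
    }
    oc <- if (length(cs$oars)) {
      a <- lapply(cs$oars, function(m) .oar_metrics(cs$dose_plan_s, m))
      b <- lapply(cs$oars, function(m) .oar_metrics(cs$dose_plan_l, m))
      compare_oar_metrics(a, b)
    } else NULL
    oar_cmp[[nm]] <- oc
    rows[[nm]] <- data.frame(
      case = nm,
      ctvl_d2 = met$d2, ctvl_d5 = met$d5, ctvl_d95 = met$d95,
      ctvl_d98 = met$d98, hotspot = met$hotspot_outside,
      accepted = verdict$accepted,
      delta_d98 = delta_d98,
      delta_under_covered = flag,
      oar_max_diff = if (is.null(oc)) NA_real_ else unname(oc$summary["max"]),
      stringsAsFactors = FALSE)
  }
  per_case <- do.call(rbind, rows)
  rownames(per_case) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(per_case, file.path(out_dir, "evaluation.csv"),
              row.names = FALSE)
    .write_json(list(per_case = per_case,
                     oar_comparisons = oar_cmp),
                file.path(out_dir, "evaluation.json"))
  }
  list(per_case = per_case, oar_comparisons = oar_cmp)
}

# -- command line ----------------------------------------------------------

.cli_opts <- function(args) {
  out <- list(positional = character(0))
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (grepl("^--", a)) {
      key <- sub("^--", "", a)
      if (i == length(args) || grepl("^--", args[[i + 1L]])) {
        out[[key]] <- TRUE
        i <- i + 1L
      } else {
        out[[key]] <- args[[i + 1L]]
        i <- i + 2L
      }
    } else {
      out$positional <- c(out$positional, a)
      i <- i + 1L
    }
  }
  # a key-value config file provides defaults; flags override
  if (!is.null(out$config)) {
    kv <- readLines(out$config, warn = FALSE)
    kv <- kv[nzchar(kv) & !grepl("^#", kv)]
    for (line in kv) {
      parts <- strsplit(line, "=", fixed = TRUE)[[1L]]
      key <- trimws(parts[1L])
      if (is.null(out[[key]])) out[[key]] <- trimws(paste(parts[-1L], collapse = "="))
    }
  }
  out
}

#' Command-line entry point
#'
#' Dispatcher behind the installed `ctvdelta` script
#' (`system.file("cli", "ctvdelta.R", package = "ctvdelta")`), with
#' subcommands `generate`, `geometry`, `evaluate` and `table4`. Flags use
#' `--key value` form and may be pre-seeded from a `--config` file of
#' `key = value` lines; defaults reproduce the package's standard
#' parameters (8 mm margin, 70 Gy prescription normalized on D95%, lung
#' window `[-1000, 0]` HU, 4 points/mm^2 Hausdorff sampling).
#'
#' @param args character vector of command-line arguments (subcommand
#'   first).
#' @return integer exit status, invisibly (0 on success).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: ctvdelta <command> [--flags]",
    "commands:",
    "  generate --out DIR [--n N] [--seed S] [--margin MM] [--fraction F]",
    "  geometry --in DIR [--out DIR] [--density PTS_PER_MM2]",
    "  evaluate --in DIR [--out DIR] [--objectives JSON]",
    "  table4   [--fixture CSV]",
    sep = "\n")
  status <- tryCatch({
    if (!length(args)) stop(usage, call. = FALSE)
    cmd <- args[[1L]]
    opt <- .cli_opts(args[-1L])
    num <- function(x, default) if (is.null(x)) default else as.numeric(x)
    if (cmd == "generate") {
      if (is.null(opt$out)) stop("generate: --out is required", call. = FALSE)
      margin <- num(opt$margin, 8)
      if (margin < 0) stop("generate: margin must be >= 0", call. = FALSE)
      spec <- phantom_spec(margin = margin,
                           volume_increase_fraction = num(opt$fraction, 0.09),
                           prescription = num(opt$prescription, 70))
      dirs <- run_generate(opt$out, n = num(opt$n, 1), spec = spec,
                           seed = as.integer(num(opt$seed, spec$seed)))
      message(sprintf("wrote %d case(s) under %s", length(dirs), opt$out))
    } else if (cmd == "geometry") {
      if (is.null(opt$`in`)) stop("geometry: --in is required", call. = FALSE)
      res <- run_geometry(opt$`in`, out_dir = opt$out,
                          sampling_density = num(opt$density, 4))
      print(res$summary)
    } else if (cmd == "evaluate") {
      if (is.null(opt$`in`)) stop("evaluate: --in is required", call. = FALSE)
      obj <- if (is.null(opt$objectives)) default_objectives() else {
        read_objectives(opt$objectives)
      }
      res <- run_evaluate(opt$`in`, out_dir = opt$out, objectives = obj)
      print(res$per_case)
    } else if (cmd == "table4") {
      res <- run_table4_analysis(path = opt$fixture)
      cat(sprintf("CTV_L plans accepted: %d of %d\n",
                  res$counts$accepted_ctvl, res$counts$n_cases))
      cat(sprintf("CTV_delta volumes under-covered: %d of %d\n",
                  res$counts$under_covered_delta, res$counts$n_cases))
    } else {
      stop(usage, call. = FALSE)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
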