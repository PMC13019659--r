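# GRO coordinate files, atom-role assignment, and the TOML-dialect
# configuration format.

#' Default atom-role table
#'
#' Maps atom and residue names to the roles the membrane CVs need.
#' Defaults cover the pseudo-lipid generator and common
#' phosphatidylcholine/water naming (phosphorus `P`/`P8`/`PO4`, water
#' oxygen `OW`/`OH2`, phosphate ester oxygens as additional polar heavy
#' atoms).
#'
#' @param phosphorus,water_oxygen,polar_extra atom-name character vectors.
#' @param lipid_residues,water_residues residue-name character vectors.
#' @return List of class `role_table`.
#' @export
role_table <- function(phosphorus = c("P", "P8", "PO4"),
                       water_oxygen = c("OW", "OH2"),
                       polar_extra = c("O11", "O12", "O13", "O14"),
                       lipid_residues = c("DMPC", "POPC", "DPPC", "LIP"),
                       water_residues = c("SOL", "TIP3", "WAT", "W")) {
  structure(list(phosphorus = phosphorus, water_oxygen = water_oxygen,
                 polar_extra = polar_extra,
                 lipid_residues = lipid_residues,
                 water_residues = water_residues),
            class = "role_table")
}

#' Read a role table from a TOML selection file
#'
#' The file carries a `[roles]` section whose keys are the arguments of
#' [role_table()]; missing keys keep their defaults.
#'
#' @param path file path.
#' @return A `role_table`.
#' @export
read_role_table <- function(path) {
  cfg <- read_toml(path)
  r <- cfg$roles
  if (is.null(r)) stop("no [roles] section in ", path)
  base <- role_table()
  for (k in names(r)) {
    if (!k %in% names(base)) stop("unknown role key: ", k)
    base[[k]] <- as.character(r[[k]])
  }
  base
}

#' Read a GRO coordinate file
#'
#' Fixed-column GRO format, nm units, orthorhombic boxes only (a box line
#' with more than three nonzero entries raises an unsupported-format
#' error).  Atom roles and lipid membership are assigned from the role
#' table by atom and residue name.
#'
#' @param path file path.
#' @param roles a [role_table()].
#' @return A [bilayer_frame()].
#' @export
read_gro <- function(path, roles = role_table()) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("malformed GRO file: fewer than 3 lines")
  title <- lines[1]
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || n < 1)
    stop("malformed GRO file at line 2: bad atom count")
  if (length(lines) < n + 3)
    stop("malformed GRO file: expected ", n + 3, " lines, found ",
         length(lines))
  atoms <- lines[3:(n + 2)]
  num <- function(s, ln) {
    v <- suppressWarnings(as.numeric(s))
    if (any(is.na(v)))
      stop("malformed GRO file at line ", ln[is.na(v)][1],
           ": unparsable coordinate")
    v
  }
  lns <- 3:(n + 2)
  res_id <- suppressWarnings(as.integer(substr(atoms, 1, 5)))
  if (any(is.na(res_id)))
    stop("malformed GRO file at line ", lns[is.na(res_id)][1],
         ": bad residue number")
  res_name <- trimws(substr(atoms, 6, 10))
  atom_name <- trimws(substr(atoms, 11, 15))
  x <- num(substr(atoms, 21, 28), lns)
  y <- num(substr(atoms, 29, 36), lns)
  z <- num(substr(atoms, 37, 44), lns)
  box_fields <- as.numeric(strsplit(trimws(lines[n + 3]), "\\s+")[[1]])
  if (any(is.na(box_fields)) || length(box_fields) < 3)
    stop("malformed GRO file at line ", n + 3, ": bad box line")
  if (length(box_fields) > 3 && any(box_fields[-(1:3)] != 0))
    stop("triclinic boxes are not supported")
  box <- box_fields[1:3]
  time <- 0
  tm <- regmatches(title, regexpr("t=\\s*[0-9.eE+-]+", title))
  if (length(tm) == 1)
    time <- as.numeric(sub("t=\\s*", "", tm))
  is_lipid <- res_name %in% roles$lipid_residues
  is_water <- res_name %in% roles$water_residues
  phosphorus <- is_lipid & atom_name %in% roles$phosphorus
  water_ox <- is_water & atom_name %in% roles$water_oxygen
  polar <- phosphorus | water_ox |
    (is_lipid & atom_name %in% roles$polar_extra)
  lipid_id <- ifelse(is_lipid, res_id, NA_integer_)
  bilayer_frame(cbind(x, y, z), box, polar_heavy = polar,
                phosphorus = phosphorus, water_oxygen = water_ox,
                lipid_id = lipid_id, atom_name = atom_name,
                res_name = res_name, res_id = res_id, time = time)
}

#' Write a frame as a GRO coordinate file
#'
#' @param frame a [bilayer_frame()].
#' @param path output file path.
#' @param title title line (frame time is appended as `t=`).
#' @return `path`, invisibly.
#' @export
write_gro <- function(frame, path, title = "poretis frame") {
  n <- nrow(frame$coords)
  an <- frame$atom_name %||% rep("X", n)
  rn <- frame$res_name %||% rep("UNK", n)
  ri <- frame$res_id %||% seq_len(n)
  lines <- c(
    sprintf("%s t= %.4f", title, frame$time),
    sprintf("%5d", n),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            ri %% 100000, substr(rn, 1, 5), substr(an, 1, 5),
            seq_len(n) %% 100000,
            frame$coords[, 1], frame$coords[, 2], frame$coords[, 3]),
    sprintf("%10.5f%10.5f%10.5f", frame$box[1], frame$box[2],
            frame$box[3]))
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a directory of GRO files as a trajectory
#'
#' Files are ordered by name; each becomes one frame.
#'
#' @param dir directory containing `*.gro` files.
#' @param roles a [role_table()].
#' @return List of [bilayer_frame()] objects.
#' @export
read_gro_trajectory <- function(dir, roles = role_table()) {
  files <- sort(list.files(dir, pattern = "\\.gro$", full.names = TRUE))
  if (length(files) == 0) stop("no .gro files in ", dir)
  lapply(files, read_gro, roles = roles)
}

# ---------------------------------------------------------------------------
# Minimal TOML dialect: [section] / [a.b] headers, key = value lines with
# strings, numbers, booleans and single-line arrays, and # comments.

strip_comment <- function(line) {
  out <- character(1)
  in_str <- FALSE
  chars <- strsplit(line, "")[[1]]
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == '"') in_str <- !in_str
    if (ch == "#" && !in_str) return(substr(line, 1, i - 1))
  }
  line
}

parse_toml_value <- function(s) {
  s <- trimws(s)
  if (s %in% c("true", "false")) return(s == "true")
  if (grepl('^".*"$', s)) return(gsub('^"|"$', "", s))
  if (grepl("^\\[.*\\]$", s)) {
    inner <- trimws(gsub("^\\[|\\]$", "", s))
    if (inner == "") return(list())
    parts <- trimws(strsplit(inner, ",")[[1]])
    vals <- lapply(parts, parse_toml_value)
    if (all(vapply(vals, is.numeric, logical(1))))
      return(unlist(vals))
    return(unlist(lapply(vals, as.character)))
  }
  v <- suppressWarnings(as.numeric(s))
  if (!is.na(v)) return(v)
  stop("cannot parse TOML value: ", s)
}

#' Read a configuration file (TOML dialect)
#'
#' Supports the subset of TOML the package writes: section headers
#' (including dotted `[a.b]`), `key = value` pairs with strings, numbers,
#' booleans and single-line arrays, and `#` comments.
#'
#' @param path file path.
#' @return Nested named list.
#' @export
read_toml <- function(path) {
  lines <- readLines(path)
  out <- list()
  section <- character(0)
  for (i in seq_along(lines)) {
    line <- trimws(strip_comment(lines[i]))
    if (line == "") next
    if (grepl("^\\[.*\\]$", line)) {
      section <- strsplit(gsub("^\\[|\\]$", "", line), ".",
                          fixed = TRUE)[[1]]
      next
    }
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 0) stop("malformed line ", i, " in ", path, ": ", line)
    key <- trimws(substr(line, 1, eq - 1))
    val <- parse_toml_value(substr(line, eq + 1, nchar(line)))
    keys <- c(section, key)
    out <- assign_nested(out, keys, val)
  }
  out
}

assign_nested <- function(lst, keys, val) {
  if (length(keys) == 1) {
    lst[[keys]] <- val
    return(lst)
  }
  head <- keys[1]
  if (is.null(lst[[head]])) lst[[head]] <- list()
  lst[[head]] <- assign_nested(lst[[head]], keys[-1], val)
  lst
}

format_toml_value <- function(v) {
  if (is.logical(v)) return(if (v) "true" else "false")
  if (is.character(v)) {
    if (length(v) > 1)
      return(paste0("[", paste0('"', v, '"', collapse = ", "), "]"))
    return(paste0('"', v, '"'))
  }
  if (is.numeric(v)) {
    fmt <- function(x) format(x, digits = 17, scientific = FALSE,
                              trim = TRUE)
    if (length(v) > 1)
      return(paste0("[", paste(vapply(v, fmt, character(1)),
                               collapse = ", "), "]"))
    return(fmt(v))
  }
  stop("cannot serialise value of class ", class(v)[1])
}

#' Write a nested list as a configuration file (TOML dialect)
#'
#' @param x nested named list (leaves: scalars or flat vectors).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_toml <- function(x, path) {
  lines <- character(0)
  emit <- function(lst, prefix) {
    scalars <- names(lst)[!vapply(lst, is.list, logical(1))]
    subs <- names(lst)[vapply(lst, is.list, logical(1))]
    if (length(prefix) > 0 && (length(scalars) > 0 || length(subs) == 0))
      lines <<- c(lines, paste0("[", paste(prefix, collapse = "."), "]"))
    for (k in scalars)
      lines <<- c(lines, paste0(k, " = ", format_toml_value(lst[[k]])))
    if (length(scalars) > 0) lines <<- c(lines, "")
    for (k in subs) emit(lst[[k]], c(prefix, k))
  }
  emit(x, character(0))
  writeLines(lines, path)
  invisible(path)
}

#' Serialise / restore a sampler configuration
#'
#' Round-trips a [retis_config()] through the TOML dialect losslessly.
#'
#' @param config a [retis_config()].
#' @param path file path.
#' @return [write_run_config()] returns `path`; [read_run_config()] a
#'   `retis_config`.
#' @export
write_run_config <- function(config, path) {
  x <- list(
    simulation = list(scheme = config$scheme,
                      n_cycles = config$n_cycles,
                      workers = config$workers,
                      seed = config$seed %||% -1),
    interfaces = list(lambdas = config$interfaces),
    moves = list(move = config$move, n_sub = config$n_sub,
                 max_len_factor = config$max_len_factor,
                 pexchange_every = config$pexchange_every,
                 infswap_every = config$infswap_every),
    output = list(store_lambdas = config$store_lambdas,
                  store_frames = config$store_frames))
  if (!is.null(config$wf_cap)) x$moves$wf_cap <- config$wf_cap
  if (!is.null(config$max_len)) x$moves$max_len <- config$max_len
  write_toml(x, path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- read_toml(path)
  seed <- x$simulation$seed
  if (!is.null(seed) && seed < 0) seed <- NULL
  retis_config(
    interfaces = x$interfaces$lambdas,
    scheme = x$simulation$scheme %||% "toy",
    n_cycles = x$simulation$n_cycles %||% 100,
    seed = seed,
    workers = x$simulation$workers %||% 1,
    move = x$moves$move %||% "auto",
    n_sub = x$moves$n_sub %||% 3,
    wf_cap = x$moves$wf_cap,
    max_len_factor = x$moves$max_len_factor %||% 50,
    max_len = x$moves$max_len,
    pexchange_every = x$moves$pexchange_every %||% 1,
    infswap_every = x$moves$infswap_every %||% 1,
    store_lambdas = isTRUE(x$output$store_lambdas),
    store_frames = isTRUE(x$output$store_frames))
}
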