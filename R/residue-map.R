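## Ballesteros-Weinstein residue annotation: binding functional roles
## (toggle switch, ionic lock, sodium site, polar triad, anchor, ...) to
## concrete residues and ligand atoms.

#' Load a receptor annotation config (ResidueMap) from YAML
#'
#' The config binds functional roles to residue numbers and BW indices, and
#' names the ligand atoms.  Required receptor roles (each exactly once):
#' `toggle` (6.48), `ionic_lock_arg` (3.50), `ionic_lock_glu` (6.30),
#' `tm6_ref` (6.34), `na_site` (2.50), `na_stabilizer` (7.49), `na_backup`
#' (3.39), `na_lid` (6.44), `polar_ser1` (5.44), `polar_ser2` (5.46),
#' `polar_asn` (6.55), `anchor` (3.32), `depth_anchor` (5.35), `base` (3.37).
#' Roles `vestibule`, `tm` and `hydrophobic` may occur any number of times.
#' Required ligand atom roles: `amine_n`, `indole_nh_n`, `indole_nh_h`,
#' `methoxy_o`, `core` (>= 3 atom names).
#'
#' @param path YAML file; see
#'   `system.file("extdata", "residue_map_5ht2a_synthetic.yaml",
#'   package = "GPCRswitch")` for the packaged example.
#' @return a validated [ResidueMap-class].
#' @export
loadResidueMap <- function(path) {
  .assert(file.exists(path), paste("no such file:", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$residues) || is.null(cfg$ligand))
    .err("config must declare 'residues' and 'ligand'", "config_error")
  res <- do.call(rbind, lapply(cfg$residues, function(r) {
    data.frame(resnum = as.integer(r$resnum),
               chain = as.character(r$chain %||% "A"),
               resname = as.character(r$resname %||% "UNK"),
               bw = as.character(r$bw %||% ""),
               role = as.character(r$role), stringsAsFactors = FALSE)
  }))
  roles <- cfg$ligand$atom_roles
  if (!is.null(roles))
    roles <- lapply(roles, function(a) as.character(unlist(a)))
  map <- new("ResidueMap", residues = res,
             ligandResname = as.character(cfg$ligand$resname %||% "LIG"),
             ligandChain = as.character(cfg$ligand$chain %||% "A"),
             ligandAtomRoles = roles %||% list())
  ok <- validObject(map, test = TRUE)
  if (!isTRUE(ok))
    .err(paste0("invalid residue map '", path, "': ",
                paste(ok, collapse = "; ")), "config_error")
  map
}

#' Write a ResidueMap to YAML (inverse of loadResidueMap)
#' @param map a [ResidueMap-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeResidueMap <- function(map, path) {
  res <- map@residues
  cfg <- list(
    residues = lapply(seq_len(nrow(res)), function(i)
      list(resnum = res$resnum[i], chain = res$chain[i],
           resname = res$resname[i], bw = res$bw[i], role = res$role[i])),
    ligand = list(resname = map@ligandResname, chain = map@ligandChain,
                  atom_roles = map@ligandAtomRoles))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Residue annotated with a given role
#' @param map a [ResidueMap-class].
#' @param role role name.
#' @return one-row (or multi-row for multi roles) data.frame.
#' @export
roleResidue <- function(map, role) {
  hit <- map@residues[map@residues$role == role, , drop = FALSE]
  if (!nrow(hit)) .err(paste("no residue annotated with role:", role),
                       "config_error")
  hit
}

## Atom indices of `atomNames` in residue with `role`; topology error when a
## requested atom is absent (named after the offending residue).
.roleAtomIdx <- function(topology, map, role, atomNames) {
  res <- roleResidue(map, role)
  idx <- integer(0)
  for (i in seq_len(nrow(res))) {
    hit <- which(topology$resnum == res$resnum[i] &
                   topology$chain == res$chain[i] &
                   topology$name %in% atomNames)
    idx <- c(idx, hit)
  }
  found <- unique(topology$name[idx])
  if (nrow(res) == 1L && length(setdiff(atomNames, found)))
    .err(sprintf("residue %s%d (role %s) is missing atoms: %s",
                 res$resname[1L], res$resnum[1L], role,
                 paste(setdiff(atomNames, found), collapse = ", ")),
         "topology_error")
  sort(idx)
}

## All atom indices of the ligand residue with a given ligand atom role.
.ligandRoleIdx <- function(topology, map, role, ordered = FALSE) {
  nms <- map@ligandAtomRoles[[role]]
  if (is.null(nms)) .err(paste("ligand atom role not declared:", role),
                         "config_error")
  lig <- topology$resname == map@ligandResname &
    topology$chain == map@ligandChain
  if (ordered) {
    idx <- vapply(nms, function(nm) {
      hit <- which(lig & topology$name == nm)
      if (!length(hit))
        .err(paste("ligand is missing atom:", nm), "topology_error")
      hit[1L]
    }, integer(1))
    return(unname(idx))
  }
  hit <- which(lig & topology$name %in% nms)
  if (length(hit) < length(nms))
    .err(sprintf("ligand is missing atoms: %s",
                 paste(setdiff(nms, topology$name[hit]), collapse = ", ")),
         "topology_error")
  hit
}
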