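# poremd file formats

All quantities are in reduced Lennard-Jones units (length a, energy eps,
mass m, k_B = 1; see `unit_system()` for SI equivalents). All tables are
tab-separated with a header row.

## XYZ structure / trajectory (`write_xyz`)

Per frame:

    line 1   bead count
    line 2   comment: "step <step> time <LJ time>"
    lines    <label> <x> <y> <z>      one per bead

`label` is the bead kind: P (phosphate-like), S (sugar-like), B
(base-like), C (membrane site). Frames are concatenated for trajectories
(`append = TRUE`).

## Topology table (`write_topology_table`)

One row per bead:

    bead      1-based bead index
    kind      P | S | B | C
    group     polymer | membrane
    bonded    comma-separated indices of bonded partners (FENE bonds)
    tether_k  harmonic tether stiffness; "Inf" for the immobile membrane;
              empty for polymer beads
    anchor    "x,y,z" lattice anchor of a membrane bead; empty otherwise

## Ensemble results (`write_ensemble_tsv`)

One row per trajectory:

    traj       trajectory index within the ensemble (1..N_t)
    seed       RNG seed of the trajectory (= master seed + traj)
    status     translocated | failed_slide | timeout
    tau_steps  translocation time in integration steps (NA unless
               translocated)
    tau        translocation time in LJ time units (= tau_steps * dt)

Only `translocated` rows enter translocation-time statistics.

## Force-sweep summaries (`force_sweep`)

    f          dimensionless pulling force
    n_success  successful translocations at that force
    tau        mean translocation time over successes
    tau_se     standard error of that mean

## Run configuration / manifest (YAML)

`write_run_config` writes a `units` stanza (declaring the reduced-unit
system) and a `run` stanza with every `protocol_config()` field; `.inf`
encodes an infinite value (immobile membrane, disabled failure detection).
`write_manifest` additionally embeds a `package` stanza (package version, R
version, timestamp) and optional `results` tallies by status, so a run is
re-executable from the manifest alone.
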