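# Microbead case-study scenario -- SYNTHETIC emission table.
#
# Particle-property ranges and the fragmentation-constant triangle are the
# published case-study values (radius 1-625 um and polymer density
# 854-1302 kg/m3 uniform; attachment efficiency 0.0001-1; fragmentation
# 1.6e-9 / 2.7e-8 / 1.3e-7 1/s low/mode/high).  The sector emission
# tonnages and STP parameters below are a synthetic reconstruction: the
# original inventory is a supporting-information table that is not
# redistributed here, so this file keeps its structure (six sectors;
# routes to air, direct freshwater, sewage, industrial and agricultural
# soil; an industrially dominated regional mix versus a more balanced
# continental mix; wide low/best/high release ranges dominated by the
# abrasives-to-air route) with magnitudes set to plausible EU values.
# See the methods vignette for the reasoning behind each number.
#
# Degradation constants are likewise a synthetic stand-in (slow relative
# to fragmentation: best-estimate half-life ~70 y).

name: microbeads_synthetic

particle:
  radius_um:     {min: 1, max: 625}
  density_kg_m3: {min: 854, max: 1302}
  alpha_het:     {min: 1.0e-4, max: 1, scale: log}

removal:
  k_frag_per_s: {low: 1.6e-9, mode: 2.7e-8, high: 1.3e-7}
  k_deg_per_s:  {low: 3.0e-11, mode: 3.0e-10, high: 3.0e-9}   # synthetic

stp:
  efficiency: {low: 0.85, mode: 0.95, high: 0.99}  # fraction captured from sewage
  sludge_application_fraction: 0.5                 # captured mass applied to land

# tonnes per year, triangular (low, best, high)
sectors:
  # ---- regional scale: industrial area, little agricultural use
  - {name: abrasives,        route: air,               scale: regional, low: 0.5,  best: 15,  high: 300}
  - {name: abrasives,        route: industrial_soil,   scale: regional, low: 0.1,  best: 2.5, high: 30}
  - {name: abrasives,        route: sewage,            scale: regional, low: 0,    best: 1,   high: 10}
  - {name: PCCP,             route: sewage,            scale: regional, low: 5,    best: 40,  high: 150}
  - {name: paints_coatings,  route: air,               scale: regional, low: 0.05, best: 1,   high: 10}
  - {name: paints_coatings,  route: freshwater_direct, scale: regional, low: 0.1,  best: 2,   high: 15}
  - {name: paints_coatings,  route: industrial_soil,   scale: regional, low: 0.05, best: 1.5, high: 12}
  - {name: soaps_detergents, route: sewage,            scale: regional, low: 1,    best: 10,  high: 40}
  - {name: agriculture,      route: agricultural_soil, scale: regional, low: 0.01, best: 0.5, high: 5}
  - {name: oil_gas,          route: industrial_soil,   scale: regional, low: 0.02, best: 0.5, high: 6}
  - {name: oil_gas,          route: air,               scale: regional, low: 0.01, best: 0.3, high: 3}
  # ---- continental scale: EU-balanced mix
  - {name: abrasives,        route: air,               scale: continental, low: 10,  best: 300, high: 5000}
  - {name: abrasives,        route: industrial_soil,   scale: continental, low: 2,   best: 50,  high: 600}
  - {name: abrasives,        route: sewage,            scale: continental, low: 0,   best: 20,  high: 200}
  - {name: PCCP,             route: sewage,            scale: continental, low: 100, best: 800, high: 3000}
  - {name: paints_coatings,  route: air,               scale: continental, low: 1,   best: 20,  high: 200}
  - {name: paints_coatings,  route: freshwater_direct, scale: continental, low: 2,   best: 40,  high: 300}
  - {name: paints_coatings,  route: industrial_soil,   scale: continental, low: 1,   best: 30,  high: 240}
  - {name: soaps_detergents, route: sewage,            scale: continental, low: 20,  best: 200, high: 800}
  - {name: agriculture,      route: agricultural_soil, scale: continental, low: 50,  best: 400, high: 2000}
  - {name: oil_gas,          route: industrial_soil,   scale: continental, low: 0.5, best: 10,  high: 120}
  - {name: oil_gas,          route: air,               scale: continental, low: 0.2, best: 6,   high: 60}
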