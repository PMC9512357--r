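# Stoichiometric-style CT calibration (synthetic: generic clinical-shape curve,
# not measured on any particular scanner).
# Step 1: Hounsfield number -> relative electron density (RED), piecewise linear.
# Step 2: RED -> physical density via rho = density_a * RED + density_b.
# Step 3: material index assigned by physical-density range.

density_a 1.0
density_b 0.0

# hu  relative_electron_density
[hu_to_red]
-1000  0.001
-950   0.050
-700   0.280
-500   0.470
-100   0.930
0      1.000
100    1.070
500    1.350
1000   1.650
2000   2.250
3000   2.850

# material  rho_min  rho_max  (g/cm^3; half-open [min,max) ranges)
[material_ranges]
air   0.00  0.05
lung  0.05  0.70
water 0.70  1.25
bone  1.25  99.0
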