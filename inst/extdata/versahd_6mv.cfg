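# Beam model: Versa HD-type head, 6 MV flattened
# Units: mm, MeV; positions along +z from the nominal source toward the patient.
quality flattened
calibration 2.02e-14
mlc_transmission 0.0

[geometry]
source_to_isocenter_mm 1000.0
phase_plane_mm 548.0
collimator_mm 401.8
grid_size_x 800
grid_size_y 800
grid_resolution_mm_x 0.5
grid_resolution_mm_y 0.5
grid_edge_mm_x -200.0
grid_edge_mm_y -200.0
fixed_x_jaw_mm 200.0
mlc_leaf_count 160
mlc_leaf_width_mm 5.0

# position_mm  weight  sigma_x_mm  sigma_y_mm
[sources]
0.0    0.94  1.5   1.5
150.0  0.06  24.0  24.0

# off_axis_mm  relative_intensity
[fluence_profile]
0.0    1.000
10.0   1.003
20.0   1.006
50.0   1.020
70.0   1.025
90.0   1.030
100.0  1.035
150.0  1.047
175.0  1.051
190.0  1.055
200.0  1.060
210.0  1.060
230.0  1.000
260.0  0.500
261.0  0.000
500.0  0.000

# energy_MeV  relative_intensity
[spectrum]
0.50  0.04184
1.00  0.07318
1.50  0.08604
2.00  0.07853
2.50  0.06149
3.00  0.05403
3.50  0.03800
4.00  0.02962
5.00  0.02559
6.00  0.01542

# square_field_width_mm  factor
[scatter_factors]
10.0   0.970
20.0   0.930
30.0   0.940
50.0   0.975
100.0  1.000
150.0  1.015
200.0  1.030
400.0  1.040
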