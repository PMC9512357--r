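# Beam model: Versa HD-type head, 6 MV flattening filter-free (FFF)
# Units: mm, MeV; positions along +z from the nominal source toward the patient.
quality FFF
calibration 2.18e-14
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
0.0    0.96  2.0   0.5
150.0  0.04  24.0  24.0

# off_axis_mm  relative_intensity
[fluence_profile]
0.0    1.000
20.0   0.971
50.0   0.865
70.0   0.787
90.0   0.720
100.0  0.684
150.0  0.552
175.0  0.499
190.0  0.475
200.0  0.455
210.0  0.435
225.0  0.410
240.0  0.375
250.0  0.345
255.0  0.325
258.0  0.000

# energy_MeV  relative_intensity
[spectrum]
0.50  0.08990
1.00  0.09820
1.50  0.06197
2.00  0.05149
2.50  0.04309
3.00  0.03776
3.50  0.03369
4.00  0.03032
5.00  0.02645
6.00  0.02408

# square_field_width_mm  factor
[scatter_factors]
10.0   0.980
20.0   0.980
30.0   0.960
50.0   0.985
100.0  1.000
150.0  1.000
200.0  1.015
400.0  1.020
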