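# Published reference values for the simulated maxillary premolar preparation
# model: 5 mm mesiodistal x 8 mm buccolingual base, wall heights 3/4/5 mm,
# uniform four-wall tapers 2/6/12/18 degrees, 172-style fissure bur
# (0.59 mm tip radius, 3 degree side half-angle) for supplemental grooves.
# T1: total prepared surface area (four axial walls + occlusal table), mm^2,
#     including the 0-degree uncut rectangular blocks.
# T2: two-groove augmentation per cell: surface area lost in groove placement
#     (printed as a negative value), total two-groove surface, net gain, mm^2.
# T3: per height: maximal opposing-wall taper resisting rotation about the
#     lingual margin axis (degrees), its base length (mm), the groove
#     resisting-wall taper (degrees) and the groove's reduced base length (mm).
# Note: for the height-5 / 12-degree area cell the source's table prints
# 160.0 while its results text gives 160.7; the table value is stored here.
table_id,height,taper,quantity,value
T1,3,0,total_area,118.0
T1,3,2,total_area,116.7
T1,3,6,total_area,114.4
T1,3,12,total_area,111.7
T1,3,18,total_area,109.7
T1,4,0,total_area,144.0
T1,4,2,total_area,142.3
T1,4,6,total_area,139.3
T1,4,12,total_area,135.8
T1,4,18,total_area,133.5
T1,5,0,total_area,170.0
T1,5,2,total_area,167.8
T1,5,6,total_area,164.1
T1,5,12,total_area,160.0
T1,5,18,total_area,157.4
T2,3,2,area_lost,-11.365
T2,3,2,groove_area,28.9
T2,3,2,net_gain,17.6
T2,3,6,area_lost,-11.360
T2,3,6,groove_area,32.1
T2,3,6,net_gain,20.8
T2,3,12,area_lost,-11.344
T2,3,12,groove_area,35.1
T2,3,12,net_gain,23.8
T2,3,18,area_lost,-11.319
T2,3,18,groove_area,38.7
T2,3,18,net_gain,27.4
T2,4,2,area_lost,-15.684
T2,4,2,groove_area,38.0
T2,4,2,net_gain,22.3
T2,4,6,area_lost,-15.676
T2,4,6,groove_area,41.6
T2,4,6,net_gain,25.9
T2,4,12,area_lost,-15.649
T2,4,12,groove_area,46.0
T2,4,12,net_gain,30.4
T2,4,18,area_lost,-15.603
T2,4,18,groove_area,47.7
T2,4,18,net_gain,32.0
T2,5,2,area_lost,-19.244
T2,5,2,groove_area,47.9
T2,5,2,net_gain,28.6
T2,5,6,area_lost,-19.231
T2,5,6,groove_area,52.7
T2,5,6,net_gain,33.5
T2,5,12,area_lost,-19.188
T2,5,12,groove_area,59.1
T2,5,12,net_gain,39.9
T2,5,18,area_lost,-19.117
T2,5,18,groove_area,66.3
T2,5,18,net_gain,47.2
T3,3,NA,alpha3_limit,11.0
T3,3,NA,base_length,8
T3,3,NA,groove_wall_taper,3
T3,3,NA,groove_base_length,3.41
T3,4,NA,alpha3_limit,15.0
T3,4,NA,base_length,8
T3,4,NA,groove_wall_taper,3
T3,4,NA,groove_base_length,3.41
T3,5,NA,alpha3_limit,19.3
T3,5,NA,base_length,8
T3,5,NA,groove_wall_taper,3
T3,5,NA,groove_base_length,3.41
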