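sample_id,sex,age,group,GM3,GM2,GM1,GD3,GD2,GD1,GT1
CS01,M,3,control,476.9,372.4,110.3,212.9,173.5,102.9,31.0
CS02,F,11,control,497.2,125.6,66.5,109.6,108.5,70.8,19.4
CS03,M,8,control,236.3,58.2,26.5,113.4,85.6,63.5,22.5
CS04,M,13,control,674.1,124.6,70.7,81.3,122.9,68.0,26.9
CS05,M,3,control,368.9,104.8,61.7,170.5,139.5,144.7,19.9
CS06,F,7,control,296.1,68.7,32.7,130.8,78.0,70.4,17.4
CS07,F,4 w,control,374.6,192.0,57.0,186.5,137.4,104.2,39.9
CS08,F,4,control,369.6,107.0,85.7,99.0,98.7,58.4,16.3
CS09,F,3,control,400.9,183.3,73.7,184.5,101.7,70.4,20.0
CS10,M,13,control,361.3,85.4,60.2,96.1,99.1,69.5,16.6
CS11,F,9,control,355.7,58.3,25.7,165.0,157.8,101.2,34.4
CS12,F,20,control,327.4,105.2,61.5,163.4,85.2,95.9,24.6
CS13,F,19,control,318.4,366.7,44.7,167.7,147.2,76.3,25.0
CS14,F,2 m,control,440.5,213.6,65.2,484.9,180.9,298.9,100.9
CS15,M,3 w,control,534.2,96.8,41.3,132.8,103.9,84.4,24.6
CS16,M,20,control,319.5,145.5,46.3,241.2,155.2,114.3,43.7
CS17,F,9,control,405.6,90.3,38.4,303.0,111.6,126.5,51.7
CS18,F,5 m,control,492.4,229.3,110.6,175.1,88.3,173.6,54.9
CS19,M,3,control,491.4,134.6,94.5,356.8,62.8,154.9,38.7
CS20,F,3,control,388.7,578.0,93.9,239.5,110.8,113.3,30.0
CS21,M,15,control,402.0,104.8,95.1,240.1,142.1,67.8,33.9
CS22,M,11,control,357.9,268.0,159.5,413.6,101.6,213.9,61.8
CS23,F,9,control,378.5,193.5,80.4,303.8,41.8,98.7,33.8
CS24,M,5,control,297.2,193.7,105.5,289.7,52.3,187.1,58.4
CS25,F,5 d,control,452.0,134.0,76.0,112.8,63.3,43.9,14.3
CS26,M,5,control,275.4,345.1,170.1,365.5,85.3,190.5,59.7
CS27,F,16 m,control,441.1,115.0,71.8,322.2,32.0,109.4,33.3
CS28,F,3 m,control,296.6,384.0,136.4,260.3,57.5,201.3,52.3
CS29,F,26 m,control,465.1,166.7,117.4,254.3,56.5,196.8,58.9
CS30,M,17,control,535.9,124.0,93.4,108.1,33.3,99.2,27.6
CS31,M,10,control,297.5,177.6,176.6,162.9,140.4,112.6,27.2
CS32,F,4 w,control,355.0,306.2,83.7,323.6,45.3,116.0,38.4
CS33,M,3,control,294.0,284.6,215.8,356.1,61.6,126.0,28.9
CS34,M,8,control,431.3,381.7,209.8,566.0,76.2,206.5,71.0
CS35,M,20,control,429.5,584.6,184.3,283.2,39.3,110.3,31.1
CS36,M,23,control,465.9,106.9,36.3,317.3,131.7,122.7,16.5
TSD01,F,3,Tay-Sachs,251.7,2905.3,464.8,161.2,107.2,85.2,24.0
TSD02,M,5,Tay-Sachs,224.2,1929.1,627.6,319.3,167.4,190.1,27.8
SD01,M,7,Sandhoff,199.6,1273.1,471.5,221.3,99.2,57.1,16.5
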