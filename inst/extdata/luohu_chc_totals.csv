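period,kind,variable,total
2015,input,health_workers,331
2015,input,floor_area,12984
2015,input,equipment,324
2015,input,home_beds,508
2016,input,health_workers,348
2016,input,floor_area,12984
2016,input,equipment,422
2016,input,home_beds,683
2017,input,health_workers,394
2017,input,floor_area,14184
2017,input,equipment,643
2017,input,home_beds,810
2018,input,health_workers,458
2018,input,floor_area,16866
2018,input,equipment,872
2018,input,home_beds,668
2019,input,health_workers,474
2019,input,floor_area,19190
2019,input,equipment,1102
2019,input,home_beds,604
2020,input,health_workers,531
2020,input,floor_area,20385
2020,input,equipment,1358
2020,input,home_beds,660
2021,input,health_workers,553
2021,input,floor_area,20985
2021,input,equipment,1381
2021,input,home_beds,883
2015,output,outpatient_visits,953455
2015,output,home_bed_services,388
2015,output,health_education,175766
2015,output,preventive_services,3038
2015,output,chronic_disease_mgmt,4050
2016,output,outpatient_visits,1436146
2016,output,home_bed_services,423
2016,output,health_education,192089
2016,output,preventive_services,2773
2016,output,chronic_disease_mgmt,7962
2017,output,outpatient_visits,1441371
2017,output,home_bed_services,532
2017,output,health_education,225676
2017,output,preventive_services,3220
2017,output,chronic_disease_mgmt,9287
2018,output,outpatient_visits,1236096
2018,output,home_bed_services,497
2018,output,health_education,234557
2018,output,preventive_services,3509
2018,output,chronic_disease_mgmt,15071
2019,output,outpatient_visits,1515986
2019,output,home_bed_services,707
2019,output,health_education,249084
2019,output,preventive_services,4042
2019,output,chronic_disease_mgmt,19496
2020,output,outpatient_visits,1012291
2020,output,home_bed_services,531
2020,output,health_education,278740
2020,output,preventive_services,3986
2020,output,chronic_disease_mgmt,23735
2021,output,outpatient_visits,1141298
2021,output,home_bed_services,603
2021,output,health_education,1687564
2021,output,preventive_services,6330
2021,output,chronic_disease_mgmt,28465
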