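period,kind,variable,total
2015,input,health_workers,2465
2015,input,beds,1010
2016,input,health_workers,2578
2016,input,beds,1068
2017,input,health_workers,2831
2017,input,beds,1109
2018,input,health_workers,3313
2018,input,beds,1479
2019,input,health_workers,3849
2019,input,beds,1839
2020,input,health_workers,4048
2020,input,beds,1890
2021,input,health_workers,4376
2021,input,beds,1890
2015,output,visits,2455737
2015,output,discharges,35472
2016,output,visits,2883925
2016,output,discharges,41868
2017,output,visits,3344179
2017,output,discharges,45109
2018,output,visits,3616063
2018,output,discharges,50554
2019,output,visits,4084031
2019,output,discharges,64501
2020,output,visits,3426196
2020,output,discharges,56451
2021,output,visits,4879238
2021,output,discharges,66404
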