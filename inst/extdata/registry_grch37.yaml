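regions:
  critical_region:
    chrom: chr15
    start: 22892936
    end: 27892936
  imprinting_center:
    chrom: chr15
    start: 25191000
    end: 25226000
genes:
  TUBGCP5:
    chrom: chr15
    start: 22833395
    end: 22873891
    zone: BP1-BP2
  CYFIP1:
    chrom: chr15
    start: 22892648
    end: 23003675
    zone: BP1-BP2
  NIPA2:
    chrom: chr15
    start: 23004684
    end: 23034427
    zone: BP1-BP2
  NIPA1:
    chrom: chr15
    start: 23043280
    end: 23086647
    zone: BP1-BP2
  MKRN3:
    chrom: chr15
    start: 23810454
    end: 23813166
    zone: BP2-BP3
  MAGEL2:
    chrom: chr15
    start: 23888695
    end: 23892993
    zone: BP2-BP3
  NDN:
    chrom: chr15
    start: 23930554
    end: 23932450
    zone: BP2-BP3
  NPAP1:
    chrom: chr15
    start: 24920541
    end: 24928593
    zone: BP2-BP3
  SNRPN:
    chrom: chr15
    start: 25200131
    end: 25223729
    zone: BP2-BP3
  UBE3A:
    chrom: chr15
    start: 25582396
    end: 25684128
    zone: BP2-BP3
  ATP10A:
    chrom: chr15
    start: 25923860
    end: 26108349
    zone: BP2-BP3
  GABRA5:
    chrom: chr15
    start: 27111866
    end: 27194357
    zone: BP2-BP3
  GABRG3:
    chrom: chr15
    start: 27216429
    end: 27778373
    zone: BP2-BP3
  OCA2:
    chrom: chr15
    start: 28000021
    end: 28344461
    zone: BP2-BP3
  HERC2:
    chrom: chr15
    start: 28356186
    end: 28567298
    zone: BP2-BP3
  APBA2:
    chrom: chr15
    start: 29213724
    end: 29404080
    zone: distal
breakpoints:
  BP1: 22770000
  BP2: 23280000
  BP3: 28590000
centromeres:
  chr1:
    start: 121500000
    end: 128900000
  chr2:
    start: 90500000
    end: 96800000
  chr3:
    start: 87900000
    end: 93900000
  chr4:
    start: 48200000
    end: 52700000
  chr5:
    start: 46100000
    end: 50700000
  chr6:
    start: 58700000
    end: 63300000
  chr7:
    start: 58000000
    end: 61700000
  chr8:
    start: 43100000
    end: 48100000
  chr9:
    start: 47300000
    end: 50700000
  chr10:
    start: 38000000
    end: 42300000
  chr11:
    start: 51600000
    end: 55700000
  chr12:
    start: 33300000
    end: 38200000
  chr13:
    start: 16300000
    end: 19500000
  chr14:
    start: 16100000
    end: 19100000
  chr15:
    start: 15800000
    end: 20700000
  chr16:
    start: 34600000
    end: 38600000
  chr17:
    start: 22200000
    end: 25800000
  chr18:
    start: 15400000
    end: 19000000
  chr19:
    start: 24400000
    end: 28600000
  chr20:
    start: 25600000
    end: 29400000
  chr21:
    start: 10900000
    end: 14300000
  chr22:
    start: 12200000
    end: 17900000
  chrX:
    start: 58100000
    end: 63000000
chrom_lengths:
  chr1: 249250621
  chr2: 243199373
  chr3: 198022430
  chr4: 191154276
  chr5: 180915260
  chr6: 171115067
  chr7: 159138663
  chr8: 146364022
  chr9: 141213431
  chr10: 135534747
  chr11: 135006516
  chr12: 133851895
  chr13: 115169878
  chr14: 107349540
  chr15: 102531392
  chr16: 90354753
  chr17: 81195210
  chr18: 78077248
  chr19: 59128983
  chr20: 63025520
  chr21: 48129895
  chr22: 51304566
  chrX: 155270560
masks:
  bed: segdup_15q11_mask.bed
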