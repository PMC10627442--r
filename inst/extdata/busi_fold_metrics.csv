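model,fold,acc_p,iou,dsc
GSU-Net,1,94.00,70.00,82.40
GSU-Net,2,94.20,74.90,85.70
GSU-Net,3,93.90,70.80,82.90
GSU-Net,4,93.90,71.60,83.50
GSU-Net,5,93.80,73.80,84.90
DBU-Net,1,94.70,72.40,84.00
DBU-Net,2,95.60,76.30,86.50
DBU-Net,3,94.90,75.20,85.90
DBU-Net,4,94.10,73.00,84.40
DBU-Net,5,94.20,74.80,85.60
DBU-Net-Prewitt,1,93.90,70.30,82.50
DBU-Net-Prewitt,2,95.00,73.60,84.80
DBU-Net-Prewitt,3,94.20,72.80,84.30
DBU-Net-Prewitt,4,93.60,69.10,81.70
DBU-Net-Prewitt,5,94.60,76.00,86.30
DBU-Net-Sobel,1,94.50,72.00,84.00
DBU-Net-Sobel,2,95.50,75.90,85.90
DBU-Net-Sobel,3,94.90,73.40,84.60
DBU-Net-Sobel,4,93.60,71.70,83.50
DBU-Net-Sobel,5,94.20,74.00,85.00
DBU-Net-dice,1,93.30,70.70,82.80
DBU-Net-dice,2,94.80,73.60,84.80
DBU-Net-dice,3,93.90,72.70,84.20
DBU-Net-dice,4,93.10,70.50,82.70
DBU-Net-dice,5,93.80,73.70,84.80
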