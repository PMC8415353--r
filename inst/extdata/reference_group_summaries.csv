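feature,label,mean_hv,sd_hv,mean_ssd,sd_ssd,n_hv,n_ssd
face_count,Number of Faces,2.38,1.01,1.46,0.79,34,34
width,Width (px),1017.45,46.36,976.18,78.34,34,34
height,Height (px),1038.46,68.47,1008.34,108.99,34,34
aspect_ratio,Aspect ratio,1.02,0.05,1.00,0.08,34,34
pct_nonsquare,Non-square images,56.83,27.53,65.72,28.45,34,34
mean_R,Average R,127.41,12.51,124.82,18.74,34,34
mean_G,Average G,115.85,12.28,111.62,16.63,34,34
mean_B,Average B,110.57,12.03,105.68,15.77,34,34
sd_R,SD R,66.80,4.25,65.71,7.41,34,34
sd_G,SD G,63.97,5.03,63.25,6.70,34,34
sd_B,SD B,60.88,4.95,60.08,6.22,34,34
skew_R,Skewness R,0.06,0.25,0.18,0.80,34,34
skew_G,Skewness G,0.22,0.28,0.42,0.82,34,34
skew_B,Skewness B,0.38,0.26,0.59,0.80,34,34
mean_H,Average H,30.98,14.66,25.30,15.79,34,34
mean_S,Average S,83.9,9.88,77.63,13.53,34,34
mean_V,Average V,138.82,12.26,132.06,17.78,34,34
sd_S,SD S,50.10,5.09,47.34,8.01,34,34
sd_V,SD V,65.34,4.09,65.11,7.08,34,34
skew_S,Skewness S,0.88,0.72,0.84,0.50,34,34
skew_V,Skewness V,-0.08,0.27,0.10,0.77,34,34
colorfulness,Colorfulness,41.86,5.51,37.25,7.51,34,34
follower_count,Follower,906.94,1565.53,416.00,352.87,34,34
following_count,Following,640.82,464.31,599.91,697.23,34,34
request_count,Request,9.97,16.49,12.09,12.88,34,34
hashtag_count,Hashtag,0.76,2.32,4.35,11.32,34,34
blocked_count,Blocked,5.82,9.71,8.03,16.86,34,34
close_count,Close,10.91,33.03,2.50,8.25,34,34
restricted_count,Restricted,0.03,0.17,0.03,0.17,34,34
blocked_per_month,Blocked (normalized),0.17,0.40,0.44,1.58,34,34
close_per_month,Close (normalized),0.20,0.53,0.08,0.31,34,34
follower_per_month,Follower (normalized),23.70,44.81,20.82,33.77,34,34
following_per_month,Following (normalized),16.14,22.82,21.74,26.45,34,34
follower_following_ratio,Followers/following,1.33,1.30,0.88,0.51,34,34
request_following_ratio,Request/following,0.02,0.02,0.03,0.05,34,34
usage_months,Duration of use (months),56.4,23.0,41.2,27.3,34,34
posts_per_month,Posts per month,3.6,6.4,6.0,13.5,34,34
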